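#' @keywords internal
"_PACKAGE"

#' @useDynLib popersist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dnorm plogis qlogis quantile rbinom rnorm rpois runif
#'   sd setNames pt var median rbeta
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Connected components by union-find
#'
#' Components of the graph on `n` nodes defined by an edge list.  Used to
#' dissolve overlapping observation buffers into populations and to cluster
#' same-day duplicate records.
#'
#' @param n number of nodes
#' @param edges two-column integer matrix of undirected edges (may have 0 rows)
#' @return integer vector of component labels, numbered 1.. in order of first
#'   appearance
#' @keywords internal
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nxt <- parent[x]
      parent[x] <<- root
      x <- nxt
    }
    root
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L])
      b <- find(edges[k, 2L])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

## Edges between points closer than `threshold` (planar coordinates).
## Plain pairwise scan, chunked to bound memory.
threshold_edges <- function(xy, threshold) {
  n <- nrow(xy)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  out <- vector("list", n - 1L)
  t2 <- threshold^2
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d2 <- (xy[j, 1] - xy[i, 1])^2 + (xy[j, 2] - xy[i, 2])^2
    hit <- j[d2 < t2]
    if (length(hit)) out[[i]] <- cbind(i, hit)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

## Month-day inclusion in a possibly year-wrapping closed window.
month_day_in_window <- function(dates, start_md, end_md) {
  md <- as.integer(format(dates, "%m")) * 100L + as.integer(format(dates, "%d"))
  s <- start_md[1] * 100L + start_md[2]
  e <- end_md[1] * 100L + end_md[2]
  if (s <= e) md >= s & md <= e else md >= s | md <= e
}

## Deterministic coordinate key at ~1 m precision (5 decimal places).
coord_key <- function(lon, lat, digits = 5L) {
  sprintf("%.*f_%.*f", digits, round(lon, digits), digits, round(lat, digits))
}

## Seed helper: all derived seeds stay well inside 32-bit range.
derive_seed <- function(seed, k) (as.integer(seed) + 1000L * as.integer(k)) %% 2000000000L
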