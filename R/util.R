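`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so generators are pure functions of their seed and never perturb
#' user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## shift an array by integer offsets with replicate (edge-clamp) padding;
## value at voxel i becomes x[i + off]
shift_array <- function(x, off) {
  d <- dim(x)
  stopifnot(length(off) == length(d))
  idx <- lapply(seq_along(d), function(ax)
    pmin(pmax(seq_len(d[ax]) + off[ax], 1L), d[ax]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

## separable Gaussian smoothing along every axis (sigma in voxels)
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  d <- dim(x)
  for (ax in seq_along(d)) {
    out <- array(0, d)
    for (j in seq_along(k)) {
      off <- integer(length(d))
      off[ax] <- j - r - 1L
      out <- out + k[j] * shift_array(x, off)
    }
    x <- out
  }
  x
}

## selective median: replace a voxel by its 3^d-neighbourhood median only
## when its deviation from that median is within k robust noise SDs, so
## impulse-scale noise is removed while thin high-contrast structures
## (1-voxel tubules, edges) survive; identity on noise-free volumes
selective_median <- function(x, k = 3) {
  med <- median_filter(x)
  dev <- x - med
  sig <- 1.4826 * stats::median(abs(dev))
  out <- x
  repl <- abs(dev) <= k * sig
  out[repl] <- med[repl]
  out
}

## 3x3(x3) median filter, replicate padding
median_filter <- function(x) {
  d <- dim(x)
  offs <- as.matrix(expand.grid(rep(list(-1:1), length(d))))
  m <- vapply(seq_len(nrow(offs)),
              function(i) as.vector(shift_array(x, offs[i, ])),
              numeric(length(x)))
  array(apply(m, 1L, stats::median), d)
}

## neighbourhood offsets for a given connectivity; 2D: 4 or 8, 3D: 6 or 26
connectivity_offsets <- function(ndim, connectivity) {
  g <- as.matrix(expand.grid(rep(list(-1:1), ndim)))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  face <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (ndim == 2L) {
    switch(as.character(connectivity), "4" = face, "8" = g,
           stop("2D connectivity must be 4 or 8", call. = FALSE))
  } else {
    switch(as.character(connectivity), "6" = face, "26" = g,
           stop("3D connectivity must be 6 or 26", call. = FALSE))
  }
}

#' Label connected components of a binary mask
#'
#' Works for 2D and 3D logical arrays. Adjacency is expressed as a graph over
#' foreground voxels and components are extracted with [igraph::components()].
#'
#' @param mask logical array (2D or 3D).
#' @param connectivity 4/8 (2D) or 6/26 (3D) neighbourhood.
#' @return Integer array of the same shape: 0 outside the mask, component
#'   label (1..k) inside.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 2L) 8L else 26L) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("mask must be a 2D or 3D array", call. = FALSE)
  lab <- array(0L, d)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  id <- array(0L, d)
  id[fg] <- seq_along(fg)
  offs <- connectivity_offsets(length(d), connectivity)
  ## keep one offset per unordered pair (lexicographically positive half)
  keep <- apply(offs, 1L, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  offs <- offs[keep, , drop = FALSE]
  co <- arrayInd(fg, d)
  edges <- NULL
  for (i in seq_len(nrow(offs))) {
    nb <- sweep(co, 2L, offs[i, ], `+`)
    ok <- rep(TRUE, nrow(nb))
    for (ax in seq_along(d)) ok <- ok & nb[, ax] >= 1L & nb[, ax] <= d[ax]
    if (!any(ok)) next
    lin <- nb[ok, 1L]
    mult <- 1L
    for (ax in seq_along(d)[-1L]) {
      mult <- mult * d[ax - 1L]
      lin <- lin + (nb[ok, ax] - 1L) * mult
    }
    nid <- id[lin]
    src <- seq_along(fg)[ok]
    hit <- nid > 0L
    if (any(hit)) edges <- rbind(edges, cbind(src[hit], nid[hit]))
  }
  if (is.null(edges)) {
    lab[fg] <- seq_along(fg)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  lab[fg] <- as.integer(memb)
  lab
}

#' Approximately uniform unit vectors on the sphere (spherical Fibonacci)
#'
#' Generates a well-spread gradient direction set per shell, adequate for
#' diffusion tensor estimation (condition of the design matrix is close to
#' that of electrostatic-repulsion schemes for n >= 6).
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## stop() with sprintf formatting
fail <- function(...) stop(sprintf(...), call. = FALSE)
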