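# Internal helpers: seeded evaluation, 8-connected labeling, small-image
# Gaussian smoothing, and box-window sums.

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# label 8-connected components of a logical matrix; returns an integer
# matrix (0 = background). Connectivity is resolved on a pixel graph.
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  n_true <- sum(mask)
  if (n_true == 0L) return(lab)
  id <- matrix(0L, nr, nc)
  id[mask] <- seq_len(n_true)
  edges <- list()
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (s in shifts) {
    dr <- s[1]; dc <- s[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <- rbind(a[keep], b[keep])
  }
  if (length(edges)) {
    e <- do.call(cbind, edges)
    g <- igraph::make_graph(as.vector(e), n = n_true, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = n_true, directed = FALSE)
  }
  memb <- igraph::components(g)$membership
  lab[mask] <- as.integer(memb)
  lab
}

# sizes of labeled components (named by label)
component_sizes <- function(lab) {
  tab <- tabulate(lab[lab > 0L])
  tab
}

# separable Gaussian smoothing with replicate padding; safe on images
# smaller than the kernel.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, kern, margin) {
    # convolve along rows (margin = 1) or columns (margin = 2)
    if (margin == 2L) return(t(conv1(t(m), kern, 1L)))
    nr <- nrow(m)
    pad_top <- m[rep(1L, r), , drop = FALSE]
    pad_bot <- m[rep(nr, r), , drop = FALSE]
    mp <- rbind(pad_top, m, pad_bot)
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(kern))
      out <- out + kern[j] * mp[(j - 1L) + seq_len(nr), , drop = FALSE]
    out
  }
  conv1(conv1(x, k, 1L), k, 2L)
}

# ROI-weighted (normalized-convolution) Gaussian smoothing: values outside
# the ROI do not bleed into it.
gaussian_blur_roi <- function(x, roi, sigma) {
  if (sigma <= 0) return(x * roi)
  num <- gaussian_blur(x * roi, sigma)
  den <- gaussian_blur(roi * 1.0, sigma)
  out <- matrix(0, nrow(x), ncol(x))
  inside <- roi & den > 1e-12
  out[inside] <- num[inside] / den[inside]
  out
}

# sliding w x w box sum with NA outside the full-window interior
box_sum <- function(x, w) {
  r <- (w - 1L) %/% 2L
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(NA_real_, nr, nc)
  if (nr < w || nc < w) return(out)
  acc <- matrix(0, nr - w + 1L, nc - w + 1L)
  for (dr in 0:(w - 1L)) for (dc in 0:(w - 1L))
    acc <- acc + x[dr + seq_len(nr - w + 1L), dc + seq_len(nc - w + 1L),
                   drop = FALSE]
  out[r + seq_len(nr - w + 1L), r + seq_len(nc - w + 1L)] <- acc
  out
}
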