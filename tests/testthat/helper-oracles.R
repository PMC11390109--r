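# Brute-force reference implementations used as independent oracles. All are
# deliberately naive double loops / full enumerations, kept separate from the
# package's code paths.

tri_brute <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(v[r, c])) next
    diffs <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (is.na(v[rr, cc])) next
      diffs <- c(diffs, abs(v[rr, cc] - v[r, c]))
    }
    if (length(diffs)) out[r, c] <- mean(diffs)
  }
  out
}

tpi_brute <- function(v, cell, inner, outer) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(v[r, c])) next
    vals <- c()
    for (rr in 1:nr) for (cc in 1:nc) {
      d <- cell * sqrt((rr - r)^2 + (cc - c)^2)
      if (d > inner && d <= outer && !is.na(v[rr, cc])) vals <- c(vals, v[rr, cc])
    }
    if (length(vals)) out[r, c] <- v[r, c] - mean(vals)
  }
  out
}

edt_brute <- function(mask, cell) {
  nr <- nrow(mask); nc <- ncol(mask)
  ridge <- which(mask == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc)
    out[r, c] <- cell * min(sqrt((ridge[, 1] - r)^2 + (ridge[, 2] - c)^2))
  out
}

blockmean_brute <- function(v, k) {
  NR <- ceiling(nrow(v) / k); NC <- ceiling(ncol(v) / k)
  out <- matrix(NA_real_, NR, NC)
  for (R in 1:NR) for (C in 1:NC) {
    rows <- ((R - 1) * k + 1):min(nrow(v), R * k)
    cols <- ((C - 1) * k + 1):min(ncol(v), C * k)
    out[R, C] <- mean(v[rows, cols], na.rm = TRUE)
  }
  out
}

# Direct softmax enumeration of the stratum-conditioned likelihood.
clogit_brute <- function(beta, X, used, stratum) {
  nll <- 0
  grad <- rep(0, ncol(X))
  for (s in unique(stratum)) {
    i <- which(stratum == s)
    w <- exp(X[i, , drop = FALSE] %*% beta)
    p <- as.vector(w / sum(w))
    iu <- which(used[i] == 1)
    nll <- nll - log(p[iu])
    grad <- grad + colSums(p * X[i, , drop = FALSE]) - X[i[iu], ]
  }
  list(nll = nll, grad = grad)
}

kde_brute <- function(mask_grid, bandwidth) {
  ctr <- rg_centers(mask_grid)
  pts <- which(mask_grid$values == 1)
  xs <- ctr$x[pts]; ys <- ctr$y[pts]
  hx <- bandwidth[1]; hy <- bandwidth[2]
  D <- matrix(0, nrow(mask_grid$values), ncol(mask_grid$values))
  for (i in seq_along(xs))
    D <- D + dnorm(ctr$x, xs[i], hx) * dnorm(ctr$y, ys[i], hy)
  D / (sum(D) * mask_grid$cell_size^2)
}
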