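# Independent oracles and fixture builders. Everything here is written as
# plainly as possible (explicit loops, closed forms) and never calls the
# implementation under test.

# brute-force PDI: explicit double loops over pixels
brute_pdi <- function(img, subtract_nuclear = FALSE, background = 0) {
  r <- pmax(img$raster - background, 0)
  cm <- img$cell_mask
  nm <- img$nuc_mask
  if (subtract_nuclear) r[nm] <- 0
  sr <- 0; sc <- 0; n <- 0
  for (i in seq_len(nrow(nm))) for (j in seq_len(ncol(nm))) {
    if (nm[i, j]) { sr <- sr + (i - 1); sc <- sc + (j - 1); n <- n + 1 }
  }
  cr <- sr / n; cc <- sc / n
  num <- 0; den <- 0; usum <- 0; m <- 0
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    if (cm[i, j]) {
      d2 <- (i - 1 - cr)^2 + (j - 1 - cc)^2
      num <- num + r[i, j] * d2
      den <- den + r[i, j]
      usum <- usum + d2
      m <- m + 1
    }
  }
  (num / den) / (usum / m)
}

# exhaustive hypergeometric upper tail P(X >= k)
brute_hyper_upper <- function(k, N, K, n) {
  js <- max(0, k):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# hand step-up Benjamini-Hochberg
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# hand moderated t for a single gene: two groups of logcpm values,
# fixed prior (d0, s02)
hand_moderated_t <- function(ps, cb, d0, s02) {
  n1 <- length(ps); n2 <- length(cb)
  coef <- mean(ps) - mean(cb)
  dg <- n1 + n2 - 2
  s2 <- (sum((ps - mean(ps))^2) + sum((cb - mean(cb))^2)) / dg
  s2_post <- (d0 * s02 + dg * s2) / (d0 + dg)
  tstat <- coef / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = d0 + dg)
  list(log2fc = coef, t = tstat, p = p)
}

# random valid small cell image (arbitrary, non-elliptical masks)
random_small_image <- function(h = 16, w = 16) {
  repeat {
    cm <- matrix(runif(h * w) < 0.6, h, w)
    nm <- cm & matrix(runif(h * w) < 0.3, h, w)
    if (sum(cm) >= 4 && sum(nm) >= 1) break
  }
  raster <- matrix(runif(h * w, 0, 10), h, w)
  cell_image(raster, cm, nm)
}

# standard test geometry: comfortably interior ellipse pair
test_geometry <- function(h = 128, w = 128, nucleus_semi = c(15, 10),
                          offset = c(3, 5)) {
  cell_geometry(h, w, c(h / 2 - 15, w / 2 - 25), nucleus_semi, offset)
}
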