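# Shared fixtures and independent oracles used across the suite.

# Closed-form bilinear interpolation at a single (row, col) source coordinate
# (0-based, corner-aligned) — the reference the vectorized resizer is checked
# against.
bilinear_point <- function(img, r, c, ch = 1L) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r0 <- min(max(floor(r), 0), H - 2); r1 <- min(r0 + 1, H - 1)
  c0 <- min(max(floor(c), 0), W - 2); c1 <- min(c0 + 1, W - 1)
  if (H == 1) { r0 <- r1 <- 0 }
  if (W == 1) { c0 <- c1 <- 0 }
  fr <- r - r0; fc <- c - c0
  (1 - fr) * (1 - fc) * img[r0 + 1, c0 + 1, ch] +
    (1 - fr) * fc * img[r0 + 1, c1 + 1, ch] +
    fr * (1 - fc) * img[r1 + 1, c0 + 1, ch] +
    fr * fc * img[r1 + 1, c1 + 1, ch]
}

bilinear_resize_oracle <- function(img, out_h, out_w) {
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  out <- array(0, c(out_h, out_w, C))
  for (ch in seq_len(C)) for (i in seq_len(out_h)) for (j in seq_len(out_w)) {
    r <- if (out_h == 1) (H - 1) / 2 else (i - 1) * (H - 1) / (out_h - 1)
    c <- if (out_w == 1) (W - 1) / 2 else (j - 1) * (W - 1) / (out_w - 1)
    out[i, j, ch] <- bilinear_point(img, r, c, ch)
  }
  out
}

# Direct O(n^2) DFT magnitude (one-sided) — oracle for the FFT-based
# statistical features.
dft_mag_oracle <- function(x) {
  n <- length(x)
  k <- 0:(n %/% 2)
  vapply(k, function(kk)
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))), numeric(1))
}

# Brute-force per-row fusion oracles (scalar loops, no vectorization).
fuse_oracle <- function(l1, l2, rule, w = c(0.5, 0.5)) {
  out <- matrix(0, nrow(l1), ncol(l1))
  for (i in seq_len(nrow(l1))) for (j in seq_len(ncol(l1)))
    out[i, j] <- switch(rule,
      product = l1[i, j] * l2[i, j],
      sum = l1[i, j] + l2[i, j],
      weighted = w[1] * l1[i, j] + w[2] * l2[i, j])
  out
}

majority_oracle <- function(mats) {
  n <- nrow(mats[[1]]); L <- ncol(mats[[1]])
  pred <- integer(n)
  for (i in seq_len(n)) {
    votes <- vapply(mats, function(m) which.max(m[i, ]), integer(1))
    counts <- tabulate(votes, L)
    top <- which(counts == max(counts))
    if (length(top) > 1) {
      post <- vapply(top, function(cl)
        sum(vapply(mats, function(m) m[i, cl], numeric(1))), numeric(1))
      top <- top[post == max(post)]
    }
    pred[i] <- min(top) - 1L
  }
  pred
}

random_scores <- function(n, L, softmax = TRUE) {
  m <- matrix(stats::rexp(n * L), n, L)
  if (softmax) m <- m / rowSums(m)
  m
}

tiny_cfg <- function(...) synth_config(n_per_class = 15L, ...)
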