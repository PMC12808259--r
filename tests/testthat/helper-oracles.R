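# Independent reference implementations used as oracles. Deliberately naive:
# direct O(N^4) DFT sums, breadth-first flood fill, explicit ANOVA sums of
# squares, closed-form pooled t statistics. They share no code with the
# package paths they check.

# direct 2-D DFT filtering by explicit quadruple sums
dft_filter_oracle <- function(pix, mask) {
  h <- nrow(pix); w <- ncol(pix)
  FT <- matrix(complex(real = 0), h, w)
  for (u in 0:(h - 1)) for (v in 0:(w - 1)) {
    s <- 0i
    for (x in 0:(h - 1)) for (y in 0:(w - 1)) {
      s <- s + pix[x + 1, y + 1] *
        exp(-2i * pi * (u * x / h + v * y / w))
    }
    FT[u + 1, v + 1] <- s
  }
  FT <- FT * mask
  out <- matrix(0, h, w)
  for (x in 0:(h - 1)) for (y in 0:(w - 1)) {
    s <- 0i
    for (u in 0:(h - 1)) for (v in 0:(w - 1)) {
      s <- s + FT[u + 1, v + 1] *
        exp(2i * pi * (u * x / h + v * y / w))
    }
    out[x + 1, y + 1] <- Re(s) / (h * w)
  }
  out
}

# breadth-first flood fill labelling; returns list(count, sizes)
flood_fill_oracle <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  if (connectivity == 8) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  sizes <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      ci <- ((cur - 1L) %% h) + 1L
      cj <- ((cur - 1L) %/% h) + 1L
      for (k in seq_len(nrow(nb))) {
        ni <- ci + nb[k, 1]; nj <- cj + nb[k, 2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w) {
          lin <- (nj - 1L) * h + ni
          if (mask[lin] && !seen[lin]) {
            seen[lin] <- TRUE
            queue <- c(queue, lin)
          }
        }
      }
    }
    sizes <- c(sizes, size)
  }
  list(count = length(sizes), sizes = sizes)
}

# exhaustive Otsu: try all 256 bin-edge thresholds, maximize between-class
# variance, return the best threshold value
otsu_exhaustive_oracle <- function(pix) {
  cand <- (1:255) / 256
  best <- -Inf; best_t <- NA_real_
  v <- as.vector(pix)
  for (t in cand) {
    lo <- v < t
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) next
    bc <- w0 * (1 - w0) * (mean(v[lo]) - mean(v[!lo]))^2
    if (bc > best) { best <- bc; best_t <- t }
  }
  best_t
}

# ICC(3,1) from explicit sums of squares
icc31_ss_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# closed-form pooled-variance two-sample t-test
ttest_pooled_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# exact RGB -> HSV -> RGB hue rotation; V = max(R,G,B) is preserved exactly
hue_rotate_exact <- function(pix, delta) {
  r <- pix[, , 1]; g <- pix[, , 2]; b <- pix[, , 3]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  hh <- ifelse(d == 0, 0,
        ifelse(v == r, ((g - b) / d) %% 6,
        ifelse(v == g, (b - r) / d + 2, (r - g) / d + 4))) / 6
  s <- ifelse(v == 0, 0, d / v)
  hh <- (hh + delta) %% 1
  i <- floor(hh * 6)
  f <- hh * 6 - i
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  out <- array(0, dim = dim(pix))
  pick <- function(sel) {
    switch(sel,
      `0` = list(v, t, p), `1` = list(q, v, p), `2` = list(p, v, t),
      `3` = list(p, q, v), `4` = list(t, p, v), `5` = list(v, p, q))
  }
  R <- G <- B <- v
  for (sel in 0:5) {
    m <- i == sel
    ch <- pick(as.character(sel))
    R[m] <- ch[[1]][m]; G[m] <- ch[[2]][m]; B[m] <- ch[[3]][m]
  }
  out[, , 1] <- R; out[, , 2] <- G; out[, , 3] <- B
  out
}

random_mask <- function(h, w, density, seed, connectivity = 8) {
  set.seed(seed)
  gsr_mask(matrix(runif(h * w) < density, h, w), connectivity = connectivity)
}
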