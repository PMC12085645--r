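# Independent brute-force oracles, deliberately naive: plain loops and
# direct formulas, sharing no code with the package implementations.

naive_median_filter <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  up <- (k - 1) %/% 2; down <- k - 1 - up
  out <- x
  for (i in 1:H) for (j in 1:W) {
    ii <- pmin(pmax((i - up):(i + down), 1), H)
    jj <- pmin(pmax((j - up):(j + down), 1), W)
    out[i, j] <- median(x[ii, jj])
  }
  out
}

naive_pcc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

naive_ssim <- function(a, b, w = 7, L = 255) {
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in 1:(H - w + 1)) for (j in 1:(W - w + 1)) {
    pa <- as.numeric(a[i:(i + w - 1), j:(j + w - 1)])
    pb <- as.numeric(b[i:(i + w - 1), j:(j + w - 1)])
    ma <- mean(pa); mb <- mean(pb)
    va <- mean(pa^2) - ma^2; vb <- mean(pb^2) - mb^2
    cab <- mean(pa * pb) - ma * mb
    vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                ((ma^2 + mb^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

naive_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}
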