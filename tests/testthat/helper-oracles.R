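# Independent brute-force oracles, deliberately written as plain loops so they
# share no code path with the package implementation.

# Classical FCM by direct per-pixel loops: membership then center update,
# repeated `iters` times from the given centers.
brute_fcm <- function(img, K, centers, m, iters) {
  x <- as.vector(img)
  n <- length(x)
  v <- centers
  mu <- matrix(0, n, K)
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) {
      d <- (x[i] - v)^2
      if (any(d == 0)) {
        mu[i, ] <- (d == 0) / sum(d == 0)
      } else {
        w <- d^(-1 / (m - 1))
        mu[i, ] <- w / sum(w)
      }
    }
    for (j in seq_len(K)) v[j] <- sum(mu[, j]^m * x) / sum(mu[, j]^m)
  }
  list(mu = mu, centers = v)
}

# FCM objective by a plain double sum.
brute_fcm_objective <- function(img, mu, v, m) {
  x <- as.vector(img)
  total <- 0
  for (i in seq_along(x))
    for (j in seq_along(v))
      total <- total + mu[i, j]^m * (x[i] - v[j])^2
  total
}

# Fuzzy factor at one pixel by explicit neighbourhood loops.
brute_fuzzy_factor_at <- function(img, mu, v, m, i, j, k) {
  s <- 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    r <- i + di; c <- j + dj
    if (r < 1 || r > nrow(img) || c < 1 || c > ncol(img)) next
    w <- 1 / (1 + sqrt(di^2 + dj^2))
    s <- s + w * (1 - mu[r, c, k])^m * (img[r, c] - v[k])^2
  }
  s
}

# O(N^2) discrete Fourier transform of a complex sequence, normalized by N.
brute_dft <- function(s) {
  N <- length(s)
  out <- complex(N)
  for (u in 0:(N - 1)) {
    acc <- 0 + 0i
    for (k in 0:(N - 1))
      acc <- acc + s[k + 1] * exp(-2i * pi * u * k / N)
    out[u + 1] <- acc / N
  }
  out
}

# Direct 2-D convolution with a separable kernel and symmetric (reflective)
# border handling, by quadruple loop.
brute_conv2_reflect <- function(img, w) {
  r <- (length(w) - 1) / 2
  H <- nrow(img); W <- ncol(img)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in -r:r) for (b in -r:r)
      acc <- acc + w[a + r + 1] * w[b + r + 1] *
        img[refl(i + a, H), refl(j + b, W)]
    out[i, j] <- acc
  }
  out
}

# Trapezoidal quadrature by an explicit loop.
brute_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + 0.5 * (y[i] + y[i + 1]) * (x[i + 1] - x[i])
  s
}

# Central-difference derivative matching pracma::gradient conventions.
brute_gradient <- function(y, h) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / h
  g[n] <- (y[n] - y[n - 1]) / h
  for (i in 2:(n - 1)) g[i] <- (y[i + 1] - y[i - 1]) / (2 * h)
  g
}

# Disk mask helper used by several fixtures.
disk_mask <- function(n, cy, cx, r) {
  X <- matrix(seq_len(n), n, n, byrow = TRUE)
  Y <- matrix(seq_len(n), n, n)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}
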