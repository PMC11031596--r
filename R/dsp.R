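# Internal DSP layer.
#
# Filtering is zero-phase: an even-order digital Butterworth design
# (bilinear transform of the analog prototype, factored into second-order
# sections) applied forward and backward over each epoch, with odd
# (point-symmetric) reflection padding and steady-state initial conditions,
# so that post-stimulus response does not smear into the pre-stimulus
# period through startup transients. The realized magnitude response is the
# square of the one-pass design.

# Smallest 5-smooth (2^a 3^b 5^c) integer >= n; R's mixed-radix FFT is fast
# only for smooth lengths.
next_fast_len <- function(n) {
  if (n <= 2) return(2L)
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(as.integer(k))
    k <- k + 1
  }
}

# --- Butterworth design (zpk -> bilinear -> second-order sections) --------

# Group a set of roots (closed under conjugation) into conjugate / real
# pairs. Returns a list of length-2 complex vectors.
pair_roots <- function(r, tol = 1e-8) {
  pairs <- list()
  cplx <- r[Im(r) > tol]
  for (x in cplx) pairs[[length(pairs) + 1]] <- c(x, Conj(x))
  reals <- sort(Re(r[abs(Im(r)) <= tol]))
  stopifnot(length(reals) %% 2 == 0)
  for (i in seq_len(length(reals) / 2)) {
    pairs[[length(pairs) + 1]] <- complex(real = reals[c(2 * i - 1, 2 * i)])
  }
  pairs
}

# Digital Butterworth as second-order sections. kind: lowpass / highpass /
# bandstop; params in Hz; order = order of the one-pass design (even).
# Returns [n_sections x 6] matrix of (b0, b1, b2, 1, a1, a2).
butter_sos <- function(kind, params, order, fs) {
  stopifnot(order %% 2 == 0, order >= 2)
  n <- order
  # analog prototype (cutoff 1 rad/s)
  p <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
  z <- complex(0)
  k <- 1
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (kind == "lowpass") {
    wo <- warp(params[1])
    p <- p * wo
    k <- k * wo^n
  } else if (kind == "highpass") {
    wo <- warp(params[1])
    k <- k * Re(1 / prod(-p))
    p <- wo / p
    z <- rep(0 + 0i, n)
  } else if (kind == "bandstop") {
    w1 <- warp(params[1]); w2 <- warp(params[2])
    bw <- w2 - w1; wo <- sqrt(w1 * w2)
    k <- k * Re(1 / prod(-p))
    php <- (bw / 2) / p
    p <- c(php + sqrt(php^2 - wo^2), php - sqrt(php^2 - wo^2))
    z <- rep(c(1i * wo, -1i * wo), n)
  } else stop("unknown filter kind: ", kind)
  # bilinear transform
  fs2 <- 2 * fs
  k <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  # pair into sections: poles closest to the unit circle first, each with
  # the nearest available zero pair
  ppairs <- pair_roots(pd)
  zpairs <- pair_roots(zd)
  ord <- order(vapply(ppairs, function(q) -max(Mod(q)), numeric(1)))
  ppairs <- ppairs[ord]
  used <- rep(FALSE, length(zpairs))
  sos <- matrix(0, length(ppairs), 6)
  for (i in seq_along(ppairs)) {
    ctr <- mean(ppairs[[i]])
    d <- vapply(seq_along(zpairs), function(j) {
      if (used[j]) Inf else Mod(mean(zpairs[[j]]) - ctr)
    }, numeric(1))
    j <- which.min(d)
    used[j] <- TRUE
    b <- c(1, -Re(sum(zpairs[[j]])), Re(prod(zpairs[[j]])))
    a <- c(1, -Re(sum(ppairs[[i]])), Re(prod(ppairs[[i]])))
    sos[i, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# Zero-phase filter matrix columns ([samples x signals]) with a Butterworth
# design; order is the one-pass order.
sos_filtfilt <- function(x, fs, kind, params, order = 4) {
  sos <- butter_sos(kind, params, order, fs)
  ntaps <- 2L * nrow(sos) + 1L
  padlen <- min(nrow(x) - 1L, 3L * ntaps)
  sosfiltfilt_mat(sos, x, padlen)
}

# Band-limited 1/f^alpha noise, unit time-domain variance by construction
# (the spectral gain is normalized analytically, not per realization).
# Returns an [n x ncols] matrix.
pink_noise <- function(n, ncols, fs, exponent = 1, band = c(0.5, 200)) {
  s2 <- next_fast_len(n)
  f <- (seq_len(s2) - 1) * fs / s2
  f <- pmin(f, fs - f)
  h <- numeric(s2)
  sel <- f >= band[1] & f <= band[2] & f > 0
  h[sel] <- f[sel]^(-exponent / 2)
  h <- h / sqrt(mean(h^2))
  w <- matrix(stats::rnorm(s2 * ncols), s2, ncols)
  x <- Re(stats::mvfft(stats::mvfft(w) * h, inverse = TRUE)) / s2
  x[seq_len(n), , drop = FALSE]
}
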