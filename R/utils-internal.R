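# Internal numerical helpers shared across modules.

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from (seed, k); keeps results < 2^31 - 1.
mixSeed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483563) * 40014 + (as.double(k) + 1) * 40692
  as.integer(s %% 2147483563) + 1L
}

hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

# Analytic signal of each row of a channels x samples matrix (FFT method).
analyticSignal <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  ft <- t(stats::mvfft(t(x)))
  ft <- sweep(ft, 2, h, `*`)
  t(stats::mvfft(t(ft), inverse = TRUE)) / n
}

# Welch PSD of a single vector: Hann window, 50% overlap, one-sided density.
# Returns list(freq, psd).
welchVector <- function(x, fs, nperseg = min(256L, length(x)),
                        overlap = 0.5) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 8L) stop("Welch segment too short (", nperseg, " samples)")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- hannWindow(nperseg)
  scale <- fs * sum(win^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    ft <- stats::fft(seg)[seq_len(nfreq)]
    p <- (Mod(ft)^2) / scale
    # one-sided: double all bins except DC (and Nyquist when nperseg even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nperseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg,
       psd = acc / length(starts))
}

# Zero-phase Butterworth band-pass on each row of a channels x samples
# matrix. The filter is designed with signal::butter and applied as the
# squared magnitude response |H(w)|^2 in the frequency domain -- the
# response of a forward-backward (zero-phase) pass -- after odd
# (point-symmetric) reflection padding at both ends. The spectral
# implementation is exactly linear and sidesteps the rounding
# amplification of the direct-form recursion at sub-hertz band edges.
zeroPhaseBandpass <- function(x, fs, low, high, order) {
  if (high >= fs / 2) {
    stop("upper band edge ", high, " Hz violates Nyquist (fs = ", fs, " Hz)")
  }
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 3L) stop("signal too short to filter")
  npad <- min(n - 1L, 3L * max(1L, as.integer(ceiling(fs / low))))
  pre <- 2 * x[, 1] - x[, (npad + 1L):2L, drop = FALSE]
  post <- 2 * x[, n] - x[, (n - 1L):(n - npad), drop = FALSE]
  ext <- cbind(pre, x, post)
  N <- stats::nextn(ncol(ext), c(2, 3, 5))
  if (N > ncol(ext)) ext <- cbind(ext, matrix(0, nrow(x), N - ncol(ext)))
  # squared digital frequency response at the FFT bin frequencies
  z <- exp(-2i * pi * (seq_len(N) - 1) / N)
  num <- 0
  den <- 0
  zp <- rep(1 + 0i, N)
  for (k in seq_along(bf$b)) {
    num <- num + bf$b[k] * zp
    den <- den + bf$a[k] * zp
    zp <- zp * z
  }
  gain <- Mod(num / den)^2
  ft <- t(stats::mvfft(t(ext)))
  ft <- sweep(ft, 2, gain, `*`)
  out <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / N
  out[, (npad + 1L):(npad + n), drop = FALSE]
}

offDiagonal <- function(m) m[row(m) != col(m)]

stopIfNotSymmetric <- function(A, tol = 1e-10) {
  if (max(abs(A - t(A))) > tol) stop("adjacency matrix is not symmetric")
  invisible(TRUE)
}

# 32-bit FNV-1a hash of a character scalar, as 8-hex-digit string.
# Arithmetic kept in doubles (< 2^53) to emulate unsigned 32-bit ops.
fnvHash <- function(txt) {
  bytes <- utf8ToInt(enc2utf8(txt))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
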