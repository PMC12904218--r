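# STOI internals: 10 kHz working rate, 256-sample Hann frames with 50%
# overlap zero-padded to a 512 DFT, 15 one-third-octave bands with lowest
# centre 150 Hz, 384 ms (30-frame) comparison segments, -15 dB clipping of
# the normalised degraded envelope, and removal of clean frames more than
# 40 dB below the loudest frame.
STOI_FS <- 10000
STOI_FRAME <- 256L
STOI_HOP <- 128L
STOI_NFFT <- 512L
STOI_NBANDS <- 15L
STOI_MINFREQ <- 150
STOI_SEG <- 30L
STOI_BETA_DB <- -15
STOI_DYN_RANGE <- 40

stoi_hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

stoi_band_matrix <- function() {
  f <- (seq_len(STOI_NFFT %/% 2 + 1) - 1) * STOI_FS / STOI_NFFT
  H <- matrix(0, STOI_NBANDS, length(f))
  for (k in seq_len(STOI_NBANDS)) {
    cf <- STOI_MINFREQ * 2^((k - 1) / 3)
    H[k, f >= cf / 2^(1 / 6) & f < cf * 2^(1 / 6)] <- 1
  }
  H
}

stoi_frames <- function(x, n = STOI_FRAME, hop = STOI_HOP) {
  starts <- seq(1, length(x) - n + 1, by = hop)
  vapply(starts, function(s) x[s:(s + n - 1)], numeric(n))  # n x nframes
}

# drop frames whose clean energy is > 40 dB below the loudest clean frame,
# then overlap-add the kept frames of both signals back into waveforms
stoi_remove_silent <- function(clean, degraded) {
  w <- stoi_hann(STOI_FRAME)
  cf <- stoi_frames(clean) * w
  df <- stoi_frames(degraded) * w
  e <- 20 * log10(sqrt(colSums(cf^2)) + .Machine$double.xmin)
  if (max(e) < -200) stop("clean signal is silent; STOI is undefined")
  keep <- which(e > max(e) - STOI_DYN_RANGE)
  n_keep <- length(keep)
  out_len <- (n_keep - 1) * STOI_HOP + STOI_FRAME
  cr <- numeric(out_len); dr <- numeric(out_len)
  for (i in seq_len(n_keep)) {
    at <- (i - 1) * STOI_HOP
    cr[(at + 1):(at + STOI_FRAME)] <- cr[(at + 1):(at + STOI_FRAME)] + cf[, keep[i]]
    dr[(at + 1):(at + STOI_FRAME)] <- dr[(at + 1):(at + STOI_FRAME)] + df[, keep[i]]
  }
  list(clean = cr, degraded = dr, n_frames_used = n_keep)
}

stoi_band_envelope <- function(x) {
  w <- stoi_hann(STOI_FRAME)
  fr <- stoi_frames(x) * w
  nfr <- ncol(fr)
  P <- matrix(0, nfr, STOI_NFFT %/% 2 + 1)
  for (i in seq_len(nfr)) {
    X <- fft(c(fr[, i], numeric(STOI_NFFT - STOI_FRAME)))
    P[i, ] <- Mod(X[seq_len(STOI_NFFT %/% 2 + 1)])^2
  }
  sqrt(P %*% t(stoi_band_matrix()))  # frames x bands
}

#' Short-time objective intelligibility (STOI)
#'
#' Correlates short-time one-third-octave temporal envelopes of a degraded
#' signal with those of the clean reference, after per-segment
#' normalisation and clipping of the degraded envelope, and averages the
#' correlations over all bands and 384 ms segments. Identical inputs score
#' 1; the measure is invariant to a common positive gain on either signal.
#' Inputs are assumed time-aligned (compensate any known direct-path delay
#' first).
#'
#' @param clean Clean reference signal.
#' @param degraded Degraded/processed signal, same length as `clean`.
#' @param sample_rate Sampling rate of both inputs in Hz. Signals not at
#'   10 kHz are resampled internally (polyphase).
#' @return A list of class `stoi_result`: `value` (the mean correlation)
#'   and `n_frames_used` (frames kept after silent-frame removal).
#' @export
compute_stoi <- function(clean, degraded, sample_rate = 16000) {
  if (length(clean) != length(degraded))
    stop("clean and degraded must have the same length (",
         length(clean), " vs ", length(degraded), ")")
  if (sample_rate != STOI_FS) {
    g <- gcd_int(STOI_FS, round(sample_rate))
    clean <- as.numeric(signal::resample(clean, STOI_FS / g, round(sample_rate) / g))
    degraded <- as.numeric(signal::resample(degraded, STOI_FS / g, round(sample_rate) / g))
  }
  min_len <- STOI_FRAME + (STOI_SEG - 1) * STOI_HOP
  if (length(clean) < min_len)
    stop("signals too short for STOI: need at least ", min_len,
         " samples at 10 kHz (384 ms)")
  rs <- stoi_remove_silent(clean, degraded)
  if (length(rs$clean) < min_len)
    stop("fewer than one 384 ms segment of active speech remains")
  A <- stoi_band_envelope(rs$clean)
  B <- stoi_band_envelope(rs$degraded)
  nfr <- nrow(A)
  clip <- 1 + 10^(-STOI_BETA_DB / 20)
  total <- 0; count <- 0
  for (m in STOI_SEG:nfr) {
    seg <- (m - STOI_SEG + 1):m
    x <- A[seg, , drop = FALSE]
    y <- B[seg, , drop = FALSE]
    alpha <- sqrt(colSums(x^2) / pmax(colSums(y^2), .Machine$double.xmin))
    yc <- pmin(y * rep(alpha, each = STOI_SEG), x * clip)
    xm <- sweep(x, 2, colMeans(x))
    ym <- sweep(yc, 2, colMeans(yc))
    denom <- sqrt(colSums(xm^2) * colSums(ym^2))
    r <- colSums(xm * ym) / pmax(denom, .Machine$double.xmin)
    r[denom == 0] <- 0
    total <- total + sum(r)
    count <- count + length(r)
  }
  structure(list(value = total / count, n_frames_used = rs$n_frames_used),
            class = "stoi_result")
}

#' @export
print.stoi_result <- function(x, ...) {
  cat(sprintf("STOI = %.4f (%d frames used)\n", x$value, x$n_frames_used))
  invisible(x)
}

#' STOI over a matched set of sentences
#'
#' @param clean_set List of clean signals.
#' @param degraded_set List of degraded signals, matched one-to-one.
#' @param sample_rate Hz, common to all signals.
#' @return A list of class `stoi_batch`: `per_sentence` (data frame with a
#'   `stoi` column), `mean`, and `sd`.
#' @export
batch_stoi <- function(clean_set, degraded_set, sample_rate = 16000) {
  if (length(clean_set) == 0) stop("empty sentence set")
  if (length(clean_set) != length(degraded_set))
    stop("clean and degraded sets differ in length")
  v <- vapply(seq_along(clean_set), function(i)
    compute_stoi(clean_set[[i]], degraded_set[[i]], sample_rate)$value,
    numeric(1))
  structure(list(per_sentence = data.frame(sentence = seq_along(v), stoi = v),
                 mean = mean(v), sd = if (length(v) > 1) sd(v) else 0),
            class = "stoi_batch")
}

#' @export
print.stoi_batch <- function(x, ...) {
  cat(sprintf("STOI over %d sentences: mean %.4f, SD %.4f\n",
              nrow(x$per_sentence), x$mean, x$sd))
  invisible(x)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
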