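#' STFT analysis/synthesis configuration
#'
#' Short-time Fourier transform settings shared by the dereverberation and
#' post-filter stages. The default 32 ms square-root Hann window with an
#' 8 ms hop at 16 kHz keeps the algorithmic latency of a one-frame
#' lookahead system near 40 ms. The square-root window is applied at both
#' analysis and synthesis, so overlap-add reconstruction stays exact under
#' spectral modification (the squared window satisfies constant overlap-add
#' at hops that divide the window length).
#'
#' @param window_ms Analysis window length in milliseconds.
#' @param hop_ms Hop between adjacent frames in milliseconds.
#' @param sample_rate Hz.
#' @param fft_size DFT length in samples; defaults to the window length.
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_ms = 32, hop_ms = 8, sample_rate = 16000,
                        fft_size = NULL) {
  window_length <- round(window_ms * sample_rate / 1000)
  hop <- round(hop_ms * sample_rate / 1000)
  if (is.null(fft_size)) fft_size <- window_length
  stopifnot(hop >= 1, hop <= window_length, fft_size >= window_length)
  if (window_length %% hop != 0)
    stop("hop must divide the window length for constant overlap-add")
  n <- seq_len(window_length) - 1
  window <- sqrt(0.5 - 0.5 * cos(2 * pi * n / window_length))  # periodic Hann
  structure(list(window_length = window_length, hop = hop,
                 fft_size = fft_size, sample_rate = sample_rate,
                 window = window),
            class = "stft_config")
}

#' Forward STFT
#'
#' Windows the signal into overlapping frames (zero-padded at both ends so
#' every sample is fully covered) and transforms each frame. The returned
#' object carries everything needed for exact reconstruction by
#' [stft_synthesize()].
#'
#' @param x Real signal vector, at least one window long.
#' @param config An [stft_config()].
#' @return An object of class `stft_frames`: complex matrix `values`
#'   (frames x bins, `bins = fft_size/2 + 1`), plus `config` and
#'   `original_length`.
#' @export
stft_analyze <- function(x, config = stft_config()) {
  stopifnot(inherits(config, "stft_config"), is.numeric(x))
  wl <- config$window_length
  if (length(x) < wl)
    stop("signal shorter than one analysis window (", wl, " samples)")
  pad <- wl
  xp <- c(numeric(pad), x, numeric(pad))
  starts <- seq(1, length(xp) - wl + 1, by = config$hop)
  nb <- config$fft_size %/% 2 + 1
  vals <- matrix(0i, nrow = length(starts), ncol = nb)
  for (i in seq_along(starts)) {
    fr <- xp[starts[i]:(starts[i] + wl - 1)] * config$window
    if (config$fft_size > wl) fr <- c(fr, numeric(config$fft_size - wl))
    vals[i, ] <- fft(fr)[seq_len(nb)]
  }
  structure(list(values = vals, config = config,
                 original_length = length(x)),
            class = "stft_frames")
}

#' Inverse STFT
#'
#' Weighted overlap-add reconstruction with the square-root window applied
#' a second time at synthesis; returns exactly `original_length` samples.
#'
#' @param frames An `stft_frames` object from [stft_analyze()] (possibly
#'   with modified `values`).
#' @return Real signal vector of length `frames$original_length`.
#' @export
stft_synthesize <- function(frames) {
  stopifnot(inherits(frames, "stft_frames"))
  cfg <- frames$config
  wl <- cfg$window_length
  nb <- cfg$fft_size %/% 2 + 1
  if (ncol(frames$values) != nb)
    stop("frame matrix has ", ncol(frames$values),
         " bins but the config implies ", nb)
  nfr <- nrow(frames$values)
  out_len <- (nfr - 1) * cfg$hop + wl
  y <- numeric(out_len)
  norm <- numeric(out_len)
  w2 <- cfg$window^2
  for (i in seq_len(nfr)) {
    spec <- frames$values[i, ]
    full <- c(spec, Conj(spec[(nb - 1):2]))
    fr <- Re(fft(full, inverse = TRUE)) / cfg$fft_size
    fr <- fr[seq_len(wl)] * cfg$window
    at <- (i - 1) * cfg$hop
    y[(at + 1):(at + wl)] <- y[(at + 1):(at + wl)] + fr
    norm[(at + 1):(at + wl)] <- norm[(at + 1):(at + wl)] + w2
  }
  ok <- norm > 1e-12
  y[ok] <- y[ok] / norm[ok]
  pad <- wl
  y[(pad + 1):(pad + frames$original_length)]
}

#' @export
print.stft_frames <- function(x, ...) {
  cat(sprintf("STFT frames: %d frames x %d bins (%d-sample window, hop %d, fs %g Hz)\n",
              nrow(x$values), ncol(x$values), x$config$window_length,
              x$config$hop, x$config$sample_rate))
  invisible(x)
}

frame_hop_seconds <- function(frames) frames$config$hop / frames$config$sample_rate
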