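REFERENCE_RMS_DB <- -26

# formant-like resonator whose centre frequency glides linearly from
# freq[1] to freq[2] across the segment (coarticulation-style movement)
gliding_resonator <- function(x, freq, bw, fs) {
  n <- length(x)
  f <- seq(freq[1], freq[2], length.out = n)
  rp <- exp(-pi * bw / fs)
  theta <- 2 * pi * f / fs
  .tv_resonator(x, -2 * rp * cos(theta), rep(rp^2, n), rep(1 - rp, n))
}

raised_cosine_window <- function(n, ramp) {
  w <- rep(1, n)
  r <- min(ramp, n %/% 2)
  if (r > 0) {
    up <- 0.5 - 0.5 * cos(pi * seq_len(r) / r)
    w[seq_len(r)] <- up
    w[(n - r + 1):n] <- rev(up)
  }
  w
}

#' Generate a synthetic Matrix-style sentence
#'
#' Produces a deterministic pseudo-sentence standing in for a closed-set
#' five-word test sentence: a harmonic voiced carrier (fundamental drifting
#' within 100-140 Hz, with natural jitter and a weak aspiration-noise
#' floor) shaped by three formant-like resonators that change per word,
#' gated into five word bursts separated by short gaps. The resulting
#' temporal envelope carries its modulation energy in the syllabic 2-8 Hz
#' range, which is exactly the structure reverberation smears and that
#' envelope-based intelligibility metrics respond to. Duration is about
#' 1.8 s; RMS is normalised to -26 dBFS.
#'
#' @param seed Integer seed; the same seed always returns bit-identical
#'   audio, and the caller's RNG state is left untouched.
#' @param sample_rate Hz.
#' @return An object of class `pseudo_sentence`: `samples`, `sample_rate`,
#'   `seed`, `duration` (seconds).
#' @export
generate_pseudo_sentence <- function(seed, sample_rate = 16000) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  fs <- sample_rate
  with_local_seed(as.integer(seed), {
    n_words <- 5L
    total_target <- min(max(rnorm(1, 1.8, 0.04), 1.65), 1.95)
    word_rel <- runif(n_words, 0.24, 0.34)
    gap_rel <- runif(n_words - 1, 0.055, 0.095)
    pad <- 0.03
    scale <- (total_target - 2 * pad) / (sum(word_rel) + sum(gap_rel))
    word_d <- word_rel * scale
    gap_d <- gap_rel * scale
    n_total <- round(total_target * fs)

    # fundamental contour: linear drift plus a slow wiggle and cycle jitter
    f0a <- runif(1, 100, 118); f0b <- runif(1, 122, 140)
    if (runif(1) < 0.5) { tmp <- f0a; f0a <- f0b; f0b <- tmp }
    tt <- seq_len(n_total) / n_total
    wig <- as.numeric(signal::filter(
      signal::butter(2, 3 / (fs / 2)), rnorm(n_total)))
    wig <- 4 * wig / max(sd(wig), 1e-12)
    jit <- as.numeric(signal::filter(
      signal::butter(2, 60 / (fs / 2)), rnorm(n_total)))
    jit <- 0.012 * jit / max(sd(jit), 1e-12)
    f0 <- (f0a + (f0b - f0a) * tt + wig) * (1 + jit)
    phase <- cumsum(f0) / fs
    n_harm <- max(3L, floor(6000 / max(f0)))
    src <- numeric(n_total)
    for (h in seq_len(n_harm)) {
      src <- src + sin(2 * pi * h * phase + runif(1, 0, 2 * pi)) / h
    }
    src <- src + 0.04 * rnorm(n_total)      # aspiration floor

    out <- numeric(n_total)
    at <- round(pad * fs)
    ramp <- round(0.035 * fs)
    glide <- function(lo, hi) {
      f0c <- runif(1, lo, hi)
      f0c * (1 + runif(2, -0.18, 0.18))   # moving start/end frequencies
    }
    fric_band <- signal::butter(2, c(1800, 6500) / (fs / 2))
    consonant <- function(nc) {
      cn <- as.numeric(signal::filter(fric_band, rnorm(nc)))
      cn / max(rms(cn), 1e-12) * runif(1, 0.3, 0.55) *
        raised_cosine_window(nc, round(0.01 * fs))
    }
    for (wd in seq_len(n_words)) {
      nw <- round(word_d[wd] * fs)
      # fricative-like unvoiced onset (and sometimes coda) around a voiced
      # nucleus with gliding formants
      n_on <- round(runif(1, 0.04, 0.07) * fs)
      n_coda <- if (runif(1) < 0.5) round(runif(1, 0.03, 0.05) * fs) else 0L
      nv <- nw - n_on - n_coda
      seg <- src[(at + n_on + 1):(at + n_on + nv)]
      seg <- gliding_resonator(seg, glide(330, 780), 90, fs)
      seg <- gliding_resonator(seg, glide(1000, 2100), 130, fs)
      seg <- gliding_resonator(seg, glide(2300, 3100), 180, fs)
      seg <- seg / max(rms(seg), 1e-12)
      # amplitude arc: syllables swell and decay rather than sit flat
      arc <- 1 - runif(1, 0.2, 0.5) * (2 * (seq_len(nv) / nv) - 1)^2
      seg <- seg * raised_cosine_window(nv, ramp) * arc * runif(1, 0.8, 1.1)
      word <- c(consonant(n_on), seg,
                if (n_coda > 0) consonant(n_coda) else numeric(0))
      out[(at + 1):(at + nw)] <- word
      at <- at + nw + if (wd < n_words) round(gap_d[wd] * fs) else 0L
    }
    out <- out - mean(out)
    out <- set_level(out, REFERENCE_RMS_DB)
    structure(list(samples = out, sample_rate = fs, seed = as.integer(seed),
                   duration = n_total / fs),
              class = "pseudo_sentence")
  })
}

#' @export
print.pseudo_sentence <- function(x, ...) {
  cat(sprintf("Pseudo-sentence (seed %d): %.2f s @ %g Hz, RMS %.1f dBFS\n",
              x$seed, x$duration, x$sample_rate, 20 * log10(rms(x$samples))))
  invisible(x)
}

#' Scale audio to a target RMS level
#'
#' Digital stand-in for presentation-level calibration: scales the signal
#' to `target_rms_db` dB relative to full scale. Idempotent.
#'
#' @param audio Nonzero numeric vector.
#' @param target_rms_db Target RMS in dBFS.
#' @return Scaled audio.
#' @export
set_level <- function(audio, target_rms_db) {
  r <- rms(audio)
  if (r == 0) stop("cannot set the level of a silent signal")
  audio * (10^(target_rms_db / 20) / r)
}

condition_label <- function(reverberant, processor) {
  base <- if (reverberant) "reverb" else "clean"
  if (processor == "none") base else paste(base, processor, sep = "_")
}

#' All six study condition labels
#' @return Character vector of the six condition names.
#' @export
study_conditions <- function() {
  c("clean", "clean_wpe", "clean_wpepf", "reverb", "reverb_wpe", "reverb_wpepf")
}

#' Apply the concatenation/extraction processing protocol
#'
#' Implements the presentation protocol: the sentence is concatenated five
#' times, optionally convolved with a room impulse response, processed as a
#' whole by the chosen dereverberation algorithm, and the segment
#' corresponding to the fourth copy is extracted (compensating the
#' direct-path delay). The three preceding copies (> 4 s of audio) give the
#' batch filter estimate its initialisation material, and the trailing copy
#' absorbs termination effects, so the extracted sentence is free of edge
#' transients.
#'
#' @param sentence A [generate_pseudo_sentence()] result.
#' @param ir Optional [impulse_response()] for the reverberant conditions.
#' @param processor `"none"`, `"wpe"`, or `"wpepf"`.
#' @param psd `"oracle"` (clean-reference weights, the idealised neural
#'   estimator) or `"iterative"`.
#' @param assumed_rt60 Post-filter decay model (s); defaults to the
#'   Schroeder estimate from `ir` when processing with `"wpepf"`.
#' @param stft,wpe Transform and predictor settings.
#' @return An object of class `processed_trial`: `condition`, `audio` (the
#'   extracted sentence, time-aligned with the clean original),
#'   `sample_rate`, `rt60_used` (`NA` for clean conditions), `seed`.
#' @export
apply_protocol <- function(sentence, ir = NULL,
                           processor = c("none", "wpe", "wpepf"),
                           psd = c("oracle", "iterative"),
                           assumed_rt60 = NULL, stft = stft_config(),
                           wpe = wpe_config()) {
  stopifnot(inherits(sentence, "pseudo_sentence"))
  processor <- match.arg(processor)
  psd <- match.arg(psd)
  reverberant <- !is.null(ir)
  if (reverberant) {
    stopifnot(inherits(ir, "impulse_response"))
    if (ir$sample_rate != sentence$sample_rate)
      stop("impulse response and sentence sample rates differ")
  }
  len <- length(sentence$samples)
  concat <- rep(sentence$samples, 5)
  dd <- 0L
  x <- concat
  if (reverberant) {
    dd <- ir$direct_index - 1L
    x <- fft_convolve(concat, ir$samples)
  }
  rt60_used <- NA_real_
  if (reverberant) {
    rt60_used <- if (!is.null(assumed_rt60)) assumed_rt60 else
      estimate_rt60(ir)
  }
  if (processor != "none") {
    clean_ref <- if (psd == "oracle") c(numeric(dd), concat) else NULL
    x <- dereverberate(
      x, mode = processor, clean = clean_ref,
      assumed_rt60 = if (processor == "wpepf") {
        if (reverberant) rt60_used else
          if (!is.null(assumed_rt60)) assumed_rt60 else 0.3
      } else NULL,
      stft = stft, wpe = wpe)
  }
  start <- 3L * len + dd
  if (start + len > length(x))
    stop("processed signal too short to extract the fourth copy")
  audio <- x[(start + 1):(start + len)]
  structure(list(condition = condition_label(reverberant, processor),
                 audio = audio, sample_rate = sentence$sample_rate,
                 rt60_used = rt60_used, seed = sentence$seed),
            class = "processed_trial")
}

# linear convolution via FFT, truncated to length(x) + length(h) - 1
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1
  nfft <- 2^ceiling(log2(n))
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
                fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}
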