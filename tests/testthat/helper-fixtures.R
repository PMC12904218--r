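# Deterministic fixtures shared across test files. Everything is built in
# code from explicit seeds (Mersenne-Twister / inversion), so the suite
# carries no binary data.

fix_seed <- function(k) {
  set.seed(k, kind = "Mersenne-Twister", normal.kind = "Inversion")
}

# Speech-shaped test pairs at the STOI working rate (10 kHz, 1.2 s):
# syllabically amplitude-modulated lowpass noise plus degradations of
# graded severity. Pair k is deterministic in k.
stoi_fixture_pair <- function(k) {
  fix_seed(1000 + k)
  fs <- 10000
  n <- 12000
  t <- (seq_len(n) - 1) / fs
  lp <- signal::butter(4, 3500 / (fs / 2))
  carrier <- as.numeric(signal::filter(lp, rnorm(n)))
  env <- 0.55 + 0.45 * sin(2 * pi * runif(1, 3, 5) * t + runif(1, 0, 2 * pi))
  clean <- carrier * env
  clean <- clean / sqrt(mean(clean^2))
  degraded <- switch(k,
    # 1: additive noise at 5 dB SNR
    clean + rnorm(n) * 10^(-5 / 20),
    # 2: exponential-tail smearing (reverberation-like)
    {
      h <- exp(-(0:1499) / 400) * rnorm(1500)
      y <- as.numeric(signal::filter(signal::Arma(h, 1), clean))
      y / sqrt(mean(y^2))
    },
    # 3: hard clipping at the 60th amplitude percentile
    pmin(pmax(clean, -quantile(abs(clean), 0.6)), quantile(abs(clean), 0.6)),
    # 4: gain + mild noise
    3 * clean + rnorm(n) * 10^(-15 / 20),
    # 5: lowpass to 1.2 kHz
    as.numeric(signal::filter(signal::butter(6, 1200 / (fs / 2)), clean)))
  list(clean = clean, degraded = as.numeric(degraded), fs = fs)
}

# Single-bin synthetic autoregressive reverberation process:
# x_t = d_t + a * x_{t-delay}, with an amplitude-modulated complex
# innovation d. Returns the process, the innovation, and the frames
# object wrapping it as one STFT bin.
ar_bin_fixture <- function(n = 400, a = 0.8, delay = 3, seed = 7) {
  fix_seed(seed)
  d <- complex(real = rnorm(n), imaginary = rnorm(n)) * rexp(n)
  x <- d
  for (t in (delay + 1):n) x[t] <- d[t] + a * x[t - delay]
  frames <- structure(
    list(values = cbind(x), config = stft_config(), original_length = 0L),
    class = "stft_frames")
  list(x = x, d = d, frames = frames, a = a, delay = delay)
}

# Exponentially decaying noise response: 60 dB decay in exactly rt60 s.
exp_decay_ir <- function(rt60 = 1, fs = 16000, dur = 1.2 * rt60, seed = 3) {
  fix_seed(seed)
  t <- (0:(round(dur * fs) - 1)) / fs
  h <- exp(-3 * log(10) / rt60 * t) * rnorm(length(t))
  impulse_response(h, fs, direct_index = 1L)
}
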