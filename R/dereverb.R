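#' WPE dereverberation configuration
#'
#' Parameters of the delayed linear-prediction (weighted prediction error)
#' dereverberation stage. The prediction delay `delay` sets the early/late
#' split: reflections arriving later than `delay` hops behind the current
#' frame are treated as predictable reverberation and removed. The default
#' delay of 6 frames (48 ms at the default STFT) keeps the predicted
#' frames clear of the 32 ms analysis-window overlap with the current
#' frame, with margin for the natural short-lag coherence of voiced
#' speech, so the predictor does not cancel clean speech. With the default
#' 10 taps the predictor then covers lags of 48-128 ms -- the
#' early-reflection range that is unhelpful for CI listeners -- and the
#' late-reverberation post-filter continues beyond it.
#'
#' @param delay Prediction delay in frames (>= 1).
#' @param order Number of prediction taps per bin (filter length, frames).
#' @param iterations Alternations between PSD re-estimation and filter
#'   re-estimation when the PSD is estimated iteratively.
#' @param psd_floor Weight floor as a fraction of the mean desired-speech
#'   power (per bin weights are `1 / pmax(psd, psd_floor * mean(psd))`).
#' @param regularization Diagonal loading of the normal equations, as a
#'   fraction of the mean autocorrelation diagonal.
#' @return An object of class `wpe_config`.
#' @export
wpe_config <- function(delay = 6, order = 10, iterations = 3,
                       psd_floor = 1e-3, regularization = 1e-6) {
  stopifnot(delay >= 1, order >= 1, iterations >= 1, psd_floor > 0,
            regularization >= 0)
  structure(list(delay = as.integer(delay), order = as.integer(order),
                 iterations = as.integer(iterations), psd_floor = psd_floor,
                 regularization = regularization),
            class = "wpe_config")
}

#' Desired-speech PSD estimate
#'
#' Per-frame, per-bin power of the non-reverberant (desired) speech, used
#' as inverse weights in the WPE least-squares filter estimate.
#'
#' @param values Nonnegative matrix, frames x bins.
#' @return An object of class `psd_estimate`.
#' @export
psd_estimate <- function(values) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0))
  structure(list(values = values), class = "psd_estimate")
}

#' Oracle desired-speech PSD from clean frames
#'
#' `psd = |clean|^2`. In the clinical chain this quantity is produced by a
#' neural estimator trained on non-reverberant speech; in this simulation
#' package the clean reference is available, so its periodogram serves as
#' the idealised estimator.
#'
#' @param clean_frames `stft_frames` of the clean (non-reverberant) signal,
#'   time-aligned with the frames to be dereverberated.
#' @return A [psd_estimate()].
#' @export
oracle_psd <- function(clean_frames) {
  stopifnot(inherits(clean_frames, "stft_frames"))
  psd_estimate(Mod(clean_frames$values)^2)
}

#' WPE dereverberation
#'
#' Per frequency bin, estimates a delayed linear predictor of the current
#' frame from frames `delay, ..., delay + order - 1` hops in the past and
#' subtracts the prediction, leaving the prediction error as the desired
#' speech:
#' `d_t = x_t - sum_l g_l x_{t - delay - l + 1}`.
#' The taps `g` solve the weighted least-squares problem with weights
#' `1 / max(psd, floor)`; low-power frames (gaps between words, where
#' reverberant tails live) therefore dominate the fit. When
#' `psd = "iterative"` the desired-speech PSD is initialised from the input
#' periodogram and alternated with filter re-estimation for
#' `config$iterations` rounds; each filter update can only decrease the
#' weighted prediction-error power under the weights it was fit with.
#'
#' @param frames `stft_frames` of the reverberant signal.
#' @param config A [wpe_config()].
#' @param psd A [psd_estimate()] (e.g. from [oracle_psd()]) or
#'   `"iterative"`.
#' @return A list of class `wpe_result`: `frames` (dereverberated
#'   `stft_frames`), `filter` (complex taps, order x bins), and
#'   `objective` (weighted prediction-error power before and after each
#'   filter update).
#' @export
wpe_dereverb <- function(frames, config = wpe_config(), psd = "iterative") {
  stopifnot(inherits(frames, "stft_frames"), inherits(config, "wpe_config"))
  X <- frames$values
  nt <- nrow(X); nb <- ncol(X)
  L <- config$order; D <- config$delay
  if (nt <= D + L)
    stop("need more than delay + order = ", D + L, " frames, got ", nt)
  iterative <- identical(psd, "iterative")
  if (!iterative) {
    if (!inherits(psd, "psd_estimate"))
      stop("psd must be a psd_estimate or \"iterative\"")
    if (!all(dim(psd$values) == dim(X)))
      stop("psd shape (", paste(dim(psd$values), collapse = "x"),
           ") does not match frames (", paste(dim(X), collapse = "x"), ")")
  }
  lambda <- if (iterative) Mod(X)^2 else psd$values
  n_iter <- if (iterative) config$iterations else 1L
  # delayed-embedding index matrix, shared across bins
  idx <- outer(seq_len(nt), D + seq_len(L) - 1L, "-")
  valid <- idx >= 1L
  idx[!valid] <- 1L
  G <- matrix(0i, nrow = L, ncol = nb)
  Dout <- X
  obj <- matrix(NA_real_, nrow = n_iter, ncol = 2,
                dimnames = list(NULL, c("before", "after")))
  for (it in seq_len(n_iter)) {
    obj_before <- 0; obj_after <- 0
    for (b in seq_len(nb)) {
      x <- X[, b]
      lam <- lambda[, b]
      w <- 1 / pmax(lam, config$psd_floor * mean(lam))
      if (!any(is.finite(w)) || all(x == 0)) { Dout[, b] <- x; next }
      Xt <- matrix(x[idx], nrow = nt, ncol = L)
      Xt[!valid] <- 0i
      XtH <- Conj(t(Xt))
      R <- XtH %*% (w * Xt)
      p <- XtH %*% (w * x)
      ridge <- config$regularization * Re(sum(diag(R))) / L
      diag(R) <- diag(R) + ridge + 1e-300
      g <- tryCatch(solve(R, p), error = function(e) {
        diag(R) <- diag(R) + max(Re(diag(R))) * 1e-8
        solve(R, p)
      })
      d_prev <- Dout[, b]
      d <- x - as.vector(Xt %*% g)
      obj_before <- obj_before + sum(w * Mod(d_prev)^2)
      obj_after <- obj_after + sum(w * Mod(d)^2)
      Dout[, b] <- d
      G[, b] <- g
    }
    obj[it, ] <- c(obj_before, obj_after)
    if (iterative && it < n_iter) lambda <- Mod(Dout)^2
  }
  out <- frames
  out$values <- Dout
  structure(list(frames = out, filter = G, objective = obj),
            class = "wpe_result")
}

#' @export
print.wpe_result <- function(x, ...) {
  cat(sprintf("WPE result: %d x %d frames, filter %d taps x %d bins, |G| = %.3g\n",
              nrow(x$frames$values), ncol(x$frames$values),
              nrow(x$filter), ncol(x$filter),
              sqrt(sum(Mod(x$filter)^2))))
  invisible(x)
}

#' Late-reverberation post-filter configuration
#'
#' @param assumed_rt60 Reverberation time driving the exponential decay
#'   model of the residual late reverberation, in seconds.
#' @param late_delay Time by which "late" energy trails the frame it is
#'   predicted from, in seconds. The default 0.128 s continues where the
#'   default WPE predictor stops (delay + order hops of 8 ms).
#' @param gain_floor Lower bound on the spectral gain in dB (< 0);
#'   limits musical noise.
#' @param smoothing One-pole smoothing constant for the power envelopes,
#'   in `[0, 1)` (0 = no smoothing).
#' @return An object of class `postfilter_config`.
#' @export
postfilter_config <- function(assumed_rt60, late_delay = 0.128,
                              gain_floor = -12, smoothing = 0.6) {
  if (!is.numeric(assumed_rt60) || assumed_rt60 <= 0)
    stop("assumed_rt60 must be a positive number of seconds")
  stopifnot(late_delay > 0, gain_floor < 0, smoothing >= 0, smoothing < 1)
  structure(list(assumed_rt60 = assumed_rt60, late_delay = late_delay,
                 gain_floor = gain_floor, smoothing = smoothing),
            class = "postfilter_config")
}

#' Late-reverberation Wiener post-filter
#'
#' Suppresses the residual reverberant tail that the linear WPE predictor
#' leaves behind. The late-reverberation power in each bin is modelled as
#' an exponentially decayed copy of the (smoothed) signal power `D` frames
#' earlier, with amplitude decay rate `delta = 3 ln(10) / assumed_rt60`:
#' `phi_late(t) = exp(-2 delta T_D) phi(t - D)`, `T_D = D` hops in seconds.
#' The applied gain is the floored power-domain Wiener rule
#' `g = max(phi - phi_late, 0) / phi`, bounded below by `gain_floor`.
#'
#' @param frames `stft_frames` to filter (typically WPE output).
#' @param config A [postfilter_config()].
#' @return Filtered `stft_frames`.
#' @export
late_reverb_postfilter <- function(frames, config) {
  stopifnot(inherits(frames, "stft_frames"),
            inherits(config, "postfilter_config"))
  hop_s <- frame_hop_seconds(frames)
  Dl <- max(1L, as.integer(round(config$late_delay / hop_s)))
  delta <- 3 * log(10) / config$assumed_rt60
  decay <- exp(-2 * delta * Dl * hop_s)
  P <- Mod(frames$values)^2
  a <- config$smoothing
  if (a > 0) {
    for (t in 2:nrow(P)) P[t, ] <- a * P[t - 1, ] + (1 - a) * P[t, ]
  }
  nt <- nrow(P)
  Plate <- matrix(0, nt, ncol(P))
  if (Dl < nt) Plate[(Dl + 1):nt, ] <- decay * P[1:(nt - Dl), ]
  g_floor <- 10^(config$gain_floor / 20)
  gain <- pmax((P - Plate), 0) / pmax(P, .Machine$double.xmin)
  gain <- pmax(gain, g_floor)
  gain[P == 0] <- 1
  out <- frames
  out$values <- frames$values * gain
  out
}

#' Dereverberate a waveform
#'
#' Convenience wrapper chaining [stft_analyze()], [wpe_dereverb()], the
#' optional [late_reverb_postfilter()] (mode `"wpepf"`), and
#' [stft_synthesize()].
#'
#' @param x Reverberant signal vector.
#' @param mode `"wpe"` or `"wpepf"`.
#' @param clean Optional clean reference signal, time-aligned with `x`;
#'   when given, its periodogram is used as the oracle desired-speech PSD,
#'   otherwise the PSD is estimated iteratively.
#' @param assumed_rt60 Reverberation time for the post-filter model
#'   (required for `"wpepf"`).
#' @param stft An [stft_config()].
#' @param wpe A [wpe_config()].
#' @param pf_late_delay,pf_gain_floor Post-filter settings, see
#'   [postfilter_config()].
#' @return Dereverberated signal, same length as `x`.
#' @export
dereverberate <- function(x, mode = c("wpe", "wpepf"), clean = NULL,
                          assumed_rt60 = NULL, stft = stft_config(),
                          wpe = wpe_config(), pf_late_delay = 0.128,
                          pf_gain_floor = -12) {
  mode <- match.arg(mode)
  frames <- stft_analyze(x, stft)
  psd <- if (is.null(clean)) {
    "iterative"
  } else {
    n <- length(x)
    cl <- if (length(clean) >= n) clean[seq_len(n)] else c(clean, numeric(n - length(clean)))
    oracle_psd(stft_analyze(cl, stft))
  }
  res <- wpe_dereverb(frames, wpe, psd)
  out <- res$frames
  if (mode == "wpepf") {
    if (is.null(assumed_rt60))
      stop("mode \"wpepf\" needs assumed_rt60")
    out <- late_reverb_postfilter(
      out, postfilter_config(assumed_rt60, late_delay = pf_late_delay,
                             gain_floor = pf_gain_floor))
  }
  stft_synthesize(out)
}
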