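SPEED_OF_SOUND <- 343

#' Predicted reverberation time of a shoebox room (Eyring)
#'
#' Eyring's formula for a room with uniform energy absorption
#' `alpha = 1 - r^2` on all six surfaces, where `r` is the magnitude of the
#' surface (pressure) reflection coefficient:
#' `RT60 = 24 ln(10) V / (-c S ln(1 - alpha))`.
#'
#' @param room_dims Numeric length-3: room length, width, height in metres.
#' @param reflection_coefficient Surface reflection coefficient magnitude,
#'   in `[0, 1)`, identical on all surfaces.
#' @param speed_of_sound Speed of sound in m/s.
#' @return Predicted RT60 in seconds.
#' @seealso [reflection_coefficient_for_rt60()] for the inverse map,
#'   [sabine_rt60()] for the low-absorption approximation.
#' @export
eyring_rt60 <- function(room_dims, reflection_coefficient,
                        speed_of_sound = SPEED_OF_SOUND) {
  stopifnot(length(room_dims) == 3, all(room_dims > 0),
            reflection_coefficient >= 0, reflection_coefficient < 1)
  V <- prod(room_dims)
  S <- 2 * (room_dims[1] * room_dims[2] + room_dims[1] * room_dims[3] +
              room_dims[2] * room_dims[3])
  alpha <- 1 - reflection_coefficient^2
  24 * log(10) * V / (-speed_of_sound * S * log1p(-alpha))
}

#' Predicted reverberation time of a shoebox room (Sabine)
#'
#' `RT60 = 24 ln(10) V / (c S alpha)`; agrees with Eyring within a few
#' percent only when absorption is low (`alpha < ~0.2`).
#'
#' @inheritParams eyring_rt60
#' @return Predicted RT60 in seconds.
#' @export
sabine_rt60 <- function(room_dims, reflection_coefficient,
                        speed_of_sound = SPEED_OF_SOUND) {
  stopifnot(length(room_dims) == 3, all(room_dims > 0),
            reflection_coefficient >= 0, reflection_coefficient < 1)
  V <- prod(room_dims)
  S <- 2 * (room_dims[1] * room_dims[2] + room_dims[1] * room_dims[3] +
              room_dims[2] * room_dims[3])
  alpha <- 1 - reflection_coefficient^2
  24 * log(10) * V / (speed_of_sound * S * alpha)
}

#' Reflection coefficient that yields a target Eyring reverberation time
#'
#' Inverts Eyring's formula for a uniform-absorption shoebox room:
#' `exp(-24 ln(10) V / (2 c S RT60))`. The map is monotone (longer
#' target, more reflective walls) and the coefficient tends to 1 as the
#' target tends to infinity (lossless limit).
#'
#' @inheritParams eyring_rt60
#' @param rt60_target Target reverberation time in seconds (> 0).
#' @return Reflection coefficient magnitude in `(0, 1)`.
#' @export
reflection_coefficient_for_rt60 <- function(room_dims, rt60_target,
                                            speed_of_sound = SPEED_OF_SOUND) {
  stopifnot(length(room_dims) == 3, all(room_dims > 0))
  if (!is.numeric(rt60_target) || length(rt60_target) != 1 || rt60_target <= 0)
    stop("rt60_target must be a single positive number of seconds")
  V <- prod(room_dims)
  S <- 2 * (room_dims[1] * room_dims[2] + room_dims[1] * room_dims[3] +
              room_dims[2] * room_dims[3])
  r <- exp(-24 * log(10) * V / (2 * speed_of_sound * S * rt60_target))
  if (r < 1e-6)
    stop(sprintf(
      "rt60_target = %g s is unattainably short for this room (required absorption ~ 1)",
      rt60_target))
  r
}

#' Specify a shoebox room simulation
#'
#' Describes the virtual room, the source, and a spherical-head receiver
#' with two point "ears" on the sphere surface, perpendicular to the
#' source direction (no diffraction or shadowing; specular reflections
#' only). Default geometry follows the evaluation room used throughout the
#' package: a 7 x 6 x 3.5 m room, source and head at 1.5 m height, placed
#' symmetrically about the room centre along the length axis, 1.9 m apart.
#'
#' @param length,width,height Room dimensions in metres.
#' @param source_position Length-3 source coordinates in metres, or `NULL`
#'   for the default placement.
#' @param head_center Length-3 head-centre coordinates in metres, or `NULL`.
#' @param head_radius Head radius in metres (ears sit on this sphere).
#' @param distance Source to head-centre distance used when positions are
#'   defaulted.
#' @param reflection_coefficient Uniform surface reflection coefficient
#'   magnitude, in `[0, 1)`.
#' @param sample_rate Simulation rate in Hz.
#' @param max_ir_length Impulse-response truncation time in seconds.
#' @param speed_of_sound Speed of sound in m/s.
#' @param rt60_nominal Optional bookkeeping: the RT60 the reflection
#'   coefficient was derived from (`NA` when specified directly).
#' @return An object of class `room_spec`.
#' @export
room_spec <- function(length = 7, width = 6, height = 3.5,
                      source_position = NULL, head_center = NULL,
                      head_radius = 0.16, distance = 1.9,
                      reflection_coefficient, sample_rate = 16000,
                      max_ir_length = 1, speed_of_sound = SPEED_OF_SOUND,
                      rt60_nominal = NA_real_) {
  dims <- c(length, width, height)
  stopifnot(all(dims > 0), head_radius > 0, sample_rate > 0, max_ir_length > 0)
  if (!is.numeric(reflection_coefficient) || reflection_coefficient < 0 ||
      reflection_coefficient >= 1)
    stop("reflection_coefficient must lie in [0, 1)")
  if (is.null(source_position))
    source_position <- c(length / 2 - distance / 2, width / 2, 1.5)
  if (is.null(head_center))
    head_center <- c(length / 2 + distance / 2, width / 2, 1.5)
  stopifnot(length(source_position) == 3, length(head_center) == 3)
  inside <- function(p, margin = 0) all(p > margin) && all(p < dims - margin)
  if (!inside(source_position)) stop("source position lies outside the room")
  if (!inside(head_center, head_radius))
    stop("head (centre + radius) does not fit inside the room")
  structure(
    list(dims = dims, source_position = as.numeric(source_position),
         head_center = as.numeric(head_center), head_radius = head_radius,
         reflection_coefficient = reflection_coefficient,
         sample_rate = sample_rate, max_ir_length = max_ir_length,
         speed_of_sound = speed_of_sound, rt60_nominal = rt60_nominal),
    class = "room_spec")
}

#' @export
print.room_spec <- function(x, ...) {
  cat(sprintf("Shoebox room %.3g x %.3g x %.3g m, r = %.4f%s\n",
              x$dims[1], x$dims[2], x$dims[3], x$reflection_coefficient,
              if (is.na(x$rt60_nominal)) ""
              else sprintf(" (nominal RT60 %.3g s)", x$rt60_nominal)))
  cat(sprintf("  source (%.2f, %.2f, %.2f), head centre (%.2f, %.2f, %.2f), d = %.3g m\n",
              x$source_position[1], x$source_position[2], x$source_position[3],
              x$head_center[1], x$head_center[2], x$head_center[3],
              sqrt(sum((x$source_position - x$head_center)^2))))
  invisible(x)
}

#' Room specification for a target reverberation time
#'
#' Builds a [room_spec()] whose reflection coefficient is inverted from the
#' target RT60. With `calibrate = FALSE` (default) the Eyring inversion is
#' used as-is: this mirrors the conventional simulation protocol in which
#' the target RT60 is a nominal label. Because a specular uniform-absorption
#' shoebox decays measurably slower than the Eyring prediction (its late
#' decay is dominated by axial and tangential image families), the Schroeder
#' RT60 measured from the simulated response runs some 20-30% above the
#' nominal value. `calibrate = TRUE` refines the coefficient by secant
#' iteration until the measured Schroeder RT60 matches the target.
#'
#' @param rt60 Target reverberation time in seconds.
#' @param calibrate Refine the coefficient against the measured Schroeder
#'   RT60 of the simulated response?
#' @param ir_length_factor Truncation time as a multiple of `rt60`.
#' @param tol Relative RT60 tolerance for calibration.
#' @param seed Sign-stream seed used for calibration simulations.
#' @param ... Passed on to [room_spec()] (geometry, sample rate, ...).
#' @return A `room_spec` with `rt60_nominal` set to `rt60`.
#' @export
room_spec_for_rt60 <- function(rt60, calibrate = FALSE,
                               ir_length_factor = 1.5, tol = 0.01,
                               seed = 1L, ...) {
  stopifnot(rt60 > 0)
  args <- list(...)
  dims <- c(
    if (is.null(args$length)) 7 else args$length,
    if (is.null(args$width)) 6 else args$width,
    if (is.null(args$height)) 3.5 else args$height)
  r <- reflection_coefficient_for_rt60(dims, rt60)
  spec <- room_spec(reflection_coefficient = r,
                    max_ir_length = max(ir_length_factor * rt60, 0.4),
                    rt60_nominal = rt60, ...)
  if (!calibrate) return(spec)
  measure <- function(rc) {
    s <- spec
    s$reflection_coefficient <- rc
    estimate_rt60(simulate_rir(s, seed = seed))
  }
  # secant iteration on the reflection coefficient; the measured RT60 is
  # smooth and monotone in r, so a handful of steps suffices
  r0 <- r
  y0 <- measure(r0) - rt60
  r1 <- reflection_coefficient_for_rt60(dims, rt60 / 1.25)
  y1 <- measure(r1) - rt60
  for (i in seq_len(8)) {
    if (abs(y1) <= tol * rt60) break
    r2 <- r1 - y1 * (r1 - r0) / (y1 - y0)
    r2 <- min(max(r2, 0.01), 0.99995)
    r0 <- r1; y0 <- y1
    r1 <- r2; y1 <- measure(r1) - rt60
  }
  if (abs(y1) > tol * rt60)
    warning(sprintf("RT60 calibration stopped at %.3g s for target %.3g s",
                    y1 + rt60, rt60))
  spec$reflection_coefficient <- r1
  spec
}

ear_position <- function(spec, ear = c("left", "right")) {
  ear <- match.arg(ear)
  u <- spec$head_center - spec$source_position
  u[3] <- 0                       # lateral offset stays horizontal
  u <- u / sqrt(sum(u^2))
  perp <- c(-u[2], u[1], 0)       # left of the propagation direction
  if (ear == "right") perp <- -perp
  spec$head_center + spec$head_radius * perp
}

#' Simulate a room impulse response (image-source method)
#'
#' Specular image-source simulation for one ear of the spherical-head
#' receiver. Reflected image taps carry seeded pseudo-random signs: with a
#' frequency-flat positive reflection coefficient, the many same-sign taps
#' that quantise into each sample would otherwise sum coherently into a
#' low-frequency pedestal that inflates the reverberant energy well above
#' the physical (incoherent) level.
#'
#' @param spec A [room_spec()].
#' @param ear `"left"` or `"right"` ear on the head sphere.
#' @param seed Integer seed for the reflection sign stream.
#' @return An `impulse_response`: list with `samples`, `sample_rate`, and
#'   `direct_index` (1-based sample of the direct-path arrival).
#' @export
simulate_rir <- function(spec, ear = c("left", "right"), seed = 1L) {
  stopifnot(inherits(spec, "room_spec"))
  ear <- match.arg(ear)
  rcv <- ear_position(spec, ear)
  if (any(rcv <= 0) || any(rcv >= spec$dims))
    stop("ear position lies outside the room")
  h <- .ism_rir(spec$dims, spec$source_position, rcv,
                spec$reflection_coefficient, spec$sample_rate,
                spec$max_ir_length, spec$speed_of_sound, as.integer(seed))
  d <- sqrt(sum((spec$source_position - rcv)^2))
  impulse_response(h, spec$sample_rate,
                   direct_index = round(d / spec$speed_of_sound *
                                          spec$sample_rate) + 1L)
}

#' Construct an impulse-response object
#'
#' @param samples Numeric vector.
#' @param sample_rate Hz.
#' @param direct_index 1-based sample index of the direct-path arrival.
#' @return An object of class `impulse_response`.
#' @export
impulse_response <- function(samples, sample_rate, direct_index) {
  stopifnot(is.numeric(samples), length(samples) > 0, all(is.finite(samples)),
            sample_rate > 0, direct_index >= 1,
            direct_index <= length(samples))
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 direct_index = as.integer(direct_index)),
            class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("Impulse response: %d samples @ %g Hz (%.3g s), direct at %.2f ms\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              (x$direct_index - 1) / x$sample_rate * 1000))
  invisible(x)
}

#' Reverberation time from an impulse response (Schroeder / T30)
#'
#' Backward-integrates the squared response into the Schroeder energy decay
#' curve, fits a line to the -5 to -35 dB span, and reports
#' `RT60 = -60 / slope` (the T30 convention: twice the 30 dB decay time).
#'
#' @param ir An [impulse_response()].
#' @return RT60 in seconds.
#' @export
estimate_rt60 <- function(ir) {
  stopifnot(inherits(ir, "impulse_response"))
  e <- ir$samples^2
  edc <- rev(cumsum(rev(e)))
  edc_db <- 10 * log10(edc / edc[1])
  # the decay range must be reached before the truncation tail, where the
  # backward integral plunges artificially
  usable <- floor(0.9 * length(edc_db))
  span <- -edc_db[usable]
  i5 <- which(edc_db <= -5)[1]
  i35 <- which(edc_db <= -35)[1]
  if (is.na(i5) || is.na(i35) || i35 > usable)
    stop(sprintf(
      "decay range is only %.1f dB; need the Schroeder curve to span at least 35 dB",
      span))
  t <- (seq_along(e) - 1) / ir$sample_rate
  sel <- i5:i35
  slope <- coef(lm(edc_db[sel] ~ t[sel]))[[2]]
  if (!is.finite(slope) || slope >= 0)
    stop("energy decay curve is not decaying over the -5 to -35 dB span")
  -60 / slope
}

#' Direct-to-reverberant ratio of an impulse response
#'
#' `DRR = 10 log10(E_direct / E_tail)` where the direct energy is taken in
#' a window of `direct_window` seconds either side of the direct-path
#' arrival and the tail is everything after that window. A response with a
#' zero tail (e.g. anechoic) returns `Inf`.
#'
#' @param ir An [impulse_response()].
#' @param direct_window Half-width of the direct-sound window in seconds.
#' @return DRR in dB (`Inf` for a zero tail).
#' @export
compute_drr <- function(ir, direct_window = 0.0025) {
  stopifnot(inherits(ir, "impulse_response"), direct_window >= 0)
  w <- round(direct_window * ir$sample_rate)
  n <- length(ir$samples)
  lo <- max(1L, ir$direct_index - w)
  hi <- min(n, ir$direct_index + w)
  e_direct <- sum(ir$samples[lo:hi]^2)
  e_tail <- if (hi >= n) 0 else sum(ir$samples[(hi + 1):n]^2)
  if (e_tail == 0) return(Inf)
  10 * log10(e_direct / e_tail)
}
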