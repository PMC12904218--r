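# Room acoustics: Eyring inversion, image-source simulation, Schroeder
# RT60 estimation, and the direct-to-reverberant ratio.

paper_room <- c(7, 6, 3.5)

test_that("Eyring inversion round-trips, is monotone, and approaches the lossless limit", {
  for (target in c(0.4, 0.7, 1.0, 1.5)) {
    r <- reflection_coefficient_for_rt60(paper_room, target)
    expect_gt(r, 0); expect_lt(r, 1)
    expect_equal(eyring_rt60(paper_room, r), target, tolerance = 1e-6)
  }
  expect_lt(reflection_coefficient_for_rt60(paper_room, 0.4),
            reflection_coefficient_for_rt60(paper_room, 1.0))
  expect_lt(reflection_coefficient_for_rt60(paper_room, 1.0),
            reflection_coefficient_for_rt60(paper_room, 1.5))
  expect_gt(reflection_coefficient_for_rt60(paper_room, 1e6), 0.9999)
  expect_error(reflection_coefficient_for_rt60(paper_room, -1), "positive")
  expect_error(reflection_coefficient_for_rt60(paper_room, 0), "positive")
})

test_that("Sabine and Eyring predictions agree at low absorption", {
  r <- reflection_coefficient_for_rt60(paper_room, 2.5)
  alpha <- 1 - r^2
  expect_lt(alpha, 0.2)
  expect_equal(sabine_rt60(paper_room, r), eyring_rt60(paper_room, r),
               tolerance = 0.05)
})

test_that("zero reflection coefficient gives a single impulse at the direct delay", {
  spec <- room_spec(reflection_coefficient = 0, max_ir_length = 0.05)
  ir <- simulate_rir(spec)
  nz <- which(ir$samples != 0)
  expect_length(nz, 1)
  expect_equal(nz, ir$direct_index)
  d <- sqrt(sum((spec$source_position - cidereverb:::ear_position(spec))^2))
  expect_equal(ir$direct_index, round(d / 343 * spec$sample_rate) + 1)
  expect_identical(compute_drr(ir), Inf)
})

test_that("room geometry is validated", {
  expect_error(room_spec(reflection_coefficient = 1.0), "\\[0, 1\\)")
  expect_error(room_spec(source_position = c(8, 3, 1.5),
                         reflection_coefficient = 0.5), "outside")
  expect_error(room_spec(head_center = c(3.5, 0.1, 1.5),
                         reflection_coefficient = 0.5), "fit inside")
  spec <- room_spec(reflection_coefficient = 0.5)
  d <- sqrt(sum((spec$source_position - spec$head_center)^2))
  expect_equal(d, 1.9)
})

test_that("Schroeder estimate recovers a constructed exponential decay and is scale invariant", {
  ir <- exp_decay_ir(rt60 = 1)
  est <- estimate_rt60(ir)
  expect_equal(est, 1, tolerance = 0.02)
  ir10 <- impulse_response(10 * ir$samples, ir$sample_rate, ir$direct_index)
  expect_equal(estimate_rt60(ir10), est, tolerance = 1e-12)
  ir_short <- exp_decay_ir(rt60 = 1, dur = 0.3)
  expect_error(estimate_rt60(ir_short), "35 dB")
  rev_ir <- impulse_response(rev(ir$samples), ir$sample_rate, 1L)
  expect_error(estimate_rt60(rev_ir))
})

test_that("Schroeder decay curve of a simulated response is monotone non-increasing", {
  spec <- room_spec_for_rt60(0.6)
  ir <- simulate_rir(spec, seed = 2)
  edc <- rev(cumsum(rev(ir$samples^2)))
  expect_true(all(diff(edc) <= 1e-12 * edc[1]))
})

test_that("DRR is 0 dB for equal energy inside and outside the direct window", {
  fs <- 16000
  w <- round(0.0025 * fs)
  h <- numeric(fs)
  h[100] <- 1                # inside the window around direct_index = 100
  h[5000] <- 1               # tail
  ir <- impulse_response(h, fs, 100L)
  expect_equal(compute_drr(ir), 0)
  # direct window really spans +/- 2.5 ms
  h2 <- h; h2[100 + w] <- 1  # second tap still inside the window
  expect_equal(compute_drr(impulse_response(h2, fs, 100L)), 10 * log10(2))
})

test_that("DRR decreases with reverberation time in the evaluation room", {
  drrs <- vapply(c(0.4, 0.7, 1.0, 1.3), function(rt) {
    compute_drr(simulate_rir(room_spec_for_rt60(rt), seed = 1))
  }, numeric(1))
  expect_true(all(diff(drrs) < 0))
})

test_that("calibrated inversion brings the measured RT60 within 10% of target", {
  for (rt in c(0.5, 1.0)) {
    spec <- room_spec_for_rt60(rt, calibrate = TRUE)
    est <- estimate_rt60(simulate_rir(spec, seed = 1))
    expect_equal(est, rt, tolerance = 0.1)
    # calibrated coefficient is below the nominal Eyring inversion
    expect_lt(spec$reflection_coefficient,
              reflection_coefficient_for_rt60(paper_room, rt))
  }
})

test_that("left and right ears sit on the head sphere perpendicular to the source", {
  spec <- room_spec(reflection_coefficient = 0.5)
  left <- cidereverb:::ear_position(spec, "left")
  right <- cidereverb:::ear_position(spec, "right")
  expect_equal(sqrt(sum((left - spec$head_center)^2)), spec$head_radius)
  expect_equal(sqrt(sum((right - spec$head_center)^2)), spec$head_radius)
  u <- spec$head_center - spec$source_position
  expect_equal(sum((left - spec$head_center) * u), 0)
  expect_false(isTRUE(all.equal(left, right)))
})
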