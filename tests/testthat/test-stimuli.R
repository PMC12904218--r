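# Synthetic sentence generator, level handling, and the concatenation /
# extraction presentation protocol.

test_that("the generator is deterministic and leaves the caller's RNG alone", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  a <- generate_pseudo_sentence(77)
  b <- generate_pseudo_sentence(77)
  expect_identical(a$samples, b$samples)
  after <- rnorm(1)
  expect_identical(before, after)
  expect_false(identical(generate_pseudo_sentence(78)$samples, a$samples))
})

test_that("sentences have plausible duration, level, and five word bursts", {
  for (s in c(1, 22, 333)) {
    sent <- generate_pseudo_sentence(s)
    expect_gte(sent$duration, 1.6)
    expect_lte(sent$duration, 2.0)
    expect_equal(20 * log10(rms(sent$samples)), -26, tolerance = 1e-6)
    # count bursts from the smoothed envelope
    env <- abs(sent$samples)
    env <- stats::filter(env, rep(1 / 800, 800), sides = 2)
    env[is.na(env)] <- 0
    on <- env > 0.25 * max(env)
    runs <- rle(as.vector(on))
    expect_equal(sum(runs$values & runs$lengths > 0.05 * 16000), 5)
  }
})

test_that("the temporal envelope is dominated by syllabic 2-8 Hz modulation", {
  for (s in c(2, 40)) {
    sent <- generate_pseudo_sentence(s)
    fs <- sent$sample_rate
    env <- abs(sent$samples)
    lp <- signal::butter(4, 30 / (fs / 2))
    env <- as.numeric(signal::filtfilt(lp, env))
    spec <- Mod(fft(env - mean(env)))^2
    f <- (seq_along(spec) - 1) * fs / length(spec)
    half <- f <= fs / 2
    tot <- sum(spec[half & f > 0.5 & f <= 30])
    syl <- sum(spec[half & f >= 2 & f <= 8])
    expect_gt(syl / tot, 0.5)
  }
})

test_that("set_level applies the definitional gain and is idempotent", {
  fix_seed(5)
  x <- rnorm(1000)
  x <- x / rms(x)                     # unit RMS
  y <- set_level(x, -26)
  expect_equal(y, x * 10^(-26 / 20), tolerance = 1e-12)
  expect_equal(set_level(y, -26), y, tolerance = 1e-12)
  expect_error(set_level(numeric(10), -26), "silent")
})

test_that("a common level change leaves STOI untouched", {
  p <- stoi_fixture_pair(1)
  v1 <- compute_stoi(p$clean, p$degraded, p$fs)$value
  v2 <- compute_stoi(set_level(p$clean, -12), set_level(p$degraded, -12),
                     p$fs)$value
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("clean unprocessed protocol is the identity on the sentence", {
  sent <- generate_pseudo_sentence(3)
  tr <- apply_protocol(sent, NULL, "none")
  expect_identical(tr$condition, "clean")
  expect_true(is.na(tr$rt60_used))
  expect_identical(tr$audio, sent$samples)
})

test_that("reverberant extraction matches the matched segment of direct convolution", {
  sent <- generate_pseudo_sentence(6)
  ir <- simulate_rir(room_spec_for_rt60(0.7), seed = 1)
  tr <- apply_protocol(sent, ir, "none")
  expect_identical(tr$condition, "reverb")
  expect_false(is.na(tr$rt60_used))
  # independent reference: full convolution via stats::convolve
  concat <- rep(sent$samples, 5)
  full <- stats::convolve(concat, rev(ir$samples), type = "open")
  len <- length(sent$samples)
  dd <- ir$direct_index - 1
  seg <- full[(3 * len + dd + 1):(3 * len + dd + len)]
  expect_equal(tr$audio, seg, tolerance = 1e-10)
})

test_that("condition labels track the processing actually applied", {
  sent <- generate_pseudo_sentence(2)
  ir <- simulate_rir(room_spec_for_rt60(0.6, ir_length_factor = 1.2), seed = 1)
  expect_identical(apply_protocol(sent, NULL, "wpe")$condition, "clean_wpe")
  tr <- apply_protocol(sent, ir, "wpepf")
  expect_identical(tr$condition, "reverb_wpepf")
  expect_false(is.na(tr$rt60_used))
})

test_that("initialising with different sentences yields the same benefit", {
  # the extracted fourth slot scores the same whether the predictor warmed
  # up on three copies of the target or on three other sentences
  fs <- 16000
  ir <- simulate_rir(room_spec_for_rt60(1.0), seed = 1)
  dd <- ir$direct_index - 1L
  diffs <- vapply(1:5, function(s) {
    target <- generate_pseudo_sentence(600 + s)
    same <- apply_protocol(target, ir, "wpe")
    others <- lapply(1:3, function(j) generate_pseudo_sentence(700 + 10 * s + j))
    concat <- c(do.call(c, lapply(others, `[[`, "samples")),
                target$samples, target$samples)
    x <- cidereverb:::fft_convolve(concat, ir$samples)
    clean_al <- c(numeric(dd), concat, numeric(length(x) - dd - length(concat)))
    y <- dereverberate(x, "wpe", clean = clean_al)
    pre <- sum(vapply(others, function(o) length(o$samples), numeric(1)))
    len <- length(target$samples)
    seg <- y[(pre + dd + 1):(pre + dd + len)]
    st_same <- compute_stoi(target$samples, same$audio, fs)$value
    st_diff <- compute_stoi(target$samples, seg, fs)$value
    st_diff - st_same
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("WAV files round-trip float samples and sample rate", {
  fix_seed(8)
  x <- rnorm(4000) * 0.2
  f <- tempfile(fileext = ".wav")
  write_wav(x, 16000, f)
  r <- read_wav(f)
  expect_equal(r$sample_rate, 16000)
  expect_equal(r$samples, x, tolerance = 1e-7)
  write_wav(x, 8000, f, bits = 16)
  r16 <- read_wav(f)
  expect_equal(r16$sample_rate, 8000)
  expect_equal(r16$samples, x, tolerance = 1e-4)
  unlink(f)
})
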