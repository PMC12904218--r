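# Listener simulation, titration, RAU transform, mixed models, ratings,
# and ICC(3,1).

test_that("RAU transform evaluates the stated formula and is symmetric and monotone", {
  # frozen by direct evaluation of the formula
  expect_equal(rau_transform(50, 100), 50.0, tolerance = 1e-4)
  expect_equal(rau_transform(0, 100), -18.3681, tolerance = 1e-4)
  expect_equal(rau_transform(100, 100), 118.3681, tolerance = 1e-4)
  x <- 0:100
  r <- rau_transform(x, 100)
  expect_true(all(diff(r) > 0))
  expect_equal(r + rev(r), rep(100, 101), tolerance = 1e-10)
  expect_equal(rau_transform(50, 100), 50, tolerance = 0.5)
  expect_error(rau_transform(-1, 100), "n_correct")
  expect_error(rau_transform(101, 100), "n_correct")
})

test_that("word scoring follows the listener's psychometric function", {
  l <- listener_profile("T1", s50 = 0.6, slope = 15, lapse = 0)
  fix_seed(41)
  draws <- simulate_word_scores(l, rep(0.6, 10000), n_words = 5)
  expect_equal(mean(draws) / 5, 0.5, tolerance = 0.01)
  expect_equal(var(draws), 5 * 0.5 * 0.5, tolerance = 0.1 * 5 * 0.25)
  l2 <- listener_profile("T2", s50 = 0.6, slope = 500, lapse = 0.04)
  fix_seed(42)
  top <- simulate_word_scores(l2, rep(1, 10000), n_words = 5)
  expect_equal(mean(top) / 5, 0.96, tolerance = 0.01)
})

test_that("50% crossing interpolation handles midpoints, exact hits, and off-grid trends", {
  ic <- cidereverb:::interpolate_crossing
  grid <- seq(0.4, 1.4, by = 0.1)
  pc <- c(95, 90, 85, 80, 75, 60, 40, 30, 25, 20, 15)
  expect_equal(ic(grid, pc), 0.95)               # 60 -> 40 midpoint
  pc2 <- pc; pc2[6] <- 50
  expect_equal(ic(grid, pc2), 0.9)               # exact grid hit
  # heading through 50 just past the grid end: extrapolated, capped
  pc3 <- seq(95, 55, length.out = 11)
  rt3 <- ic(grid, pc3)
  expect_gt(rt3, 1.4); expect_lte(rt3, 1.5)
  # hopeless track errors with the achieved range
  expect_error(ic(grid, rep(90, 11)), "90")
})

test_that("titration recovers a known 50% point from a synthetic STOI table", {
  grid <- seq(0.4, 1.4, by = 0.1)
  curve <- function(rt) 0.9 - 0.2 * (rt - 0.4)   # steep, linear, noiseless
  tab <- do.call(rbind, lapply(grid, function(rt)
    data.frame(rt60 = rt, seed = 1:10, stoi = curve(rt))))
  truth <- 0.9                                    # curve hits s50=0.8 there
  rts <- vapply(1:20, function(i) {
    l <- listener_profile(paste0("L", i), s50 = 0.8, slope = 22,
                          lapse = 0, rng_seed = 5000 + i)
    titrate_rt60_50(l, tab, grid)$rt60_50
  }, numeric(1))
  expect_equal(median(rts), truth, tolerance = 0.08)
  expect_true(all(rts > 0.6 & rts < 1.2))
})

test_that("the condition mixed model recovers known fixed effects and variance components", {
  conds <- study_conditions()
  effects <- c(0, 1, -1, -45, -30, -23)           # RAU offsets per condition
  names(effects) <- conds
  n_sub <- 15
  runs <- 100
  cover <- matrix(NA, runs, 5)
  rvar <- numeric(runs)
  for (r in seq_len(runs)) {
    fix_seed(8000 + r)
    b <- rnorm(n_sub, 0, 8)
    df <- expand.grid(subject = sprintf("S%02d", 1:n_sub),
                      condition = conds, replicate = c("test", "retest"),
                      stringsAsFactors = FALSE)
    df$rau <- 80 + effects[df$condition] + b[match(df$subject, sprintf("S%02d", 1:n_sub))] +
      rnorm(nrow(df), 0, 6)
    df$condition <- factor(df$condition, levels = conds)
    fit <- fit_condition_lmm(df)
    fe <- fit$fixed
    est <- fe[-1, "Estimate"]; se <- fe[-1, "Std. Error"]
    truth <- effects[-1]
    cover[r, ] <- abs(est - truth) <= 1.96 * se
    rvar[r] <- fit$ranef_var
  }
  expect_gte(mean(cover), 0.90)
  expect_equal(mean(rvar), 64, tolerance = 0.3 * 64)
})

test_that("Sidak and Bonferroni corrections dominate raw p values and are identity at m = 1", {
  # two-condition design: a single contrast, Sidak must equal the raw p
  fix_seed(901)
  df <- expand.grid(subject = sprintf("S%02d", 1:10),
                    condition = c("clean", "reverb"),
                    replicate = c("test", "retest"),
                    stringsAsFactors = FALSE)
  df$rau <- 60 + ifelse(df$condition == "reverb", -5, 0) +
    rnorm(nrow(df), 0, 6) +
    2 * as.integer(factor(df$subject))
  fit <- fit_condition_lmm(df)
  expect_equal(nrow(fit$pairwise), 1)
  expect_equal(fit$pairwise$p_sidak, fit$pairwise$p, tolerance = 1e-12)
  # six-condition fit: adjusted >= raw everywhere
  fix_seed(902)
  df6 <- expand.grid(subject = sprintf("S%02d", 1:8),
                     condition = study_conditions(),
                     replicate = c("test", "retest"),
                     stringsAsFactors = FALSE)
  df6$rau <- 60 + rnorm(nrow(df6), 0, 8)
  fit6 <- fit_condition_lmm(df6)
  expect_true(all(fit6$pairwise$p_sidak >= fit6$pairwise$p - 1e-12))
  expect_true(all(fit6$pairwise$p_sidak <= 1))
})

test_that("incomplete designs are rejected with the missing cells named", {
  df <- expand.grid(subject = c("S01", "S02"),
                    condition = study_conditions(),
                    stringsAsFactors = FALSE)
  df$rau <- rnorm(nrow(df), 60, 5)
  df <- df[!(df$subject == "S02" & df$condition == "reverb_wpe"), ]
  expect_error(fit_condition_lmm(df), "S02:reverb_wpe")
})

test_that("the RT60 model needs thresholds and reports the interaction test", {
  fix_seed(905)
  df <- expand.grid(subject = sprintf("S%02d", 1:12),
                    condition = c("reverb", "reverb_wpe", "reverb_wpepf"),
                    replicate = c("test", "retest"),
                    stringsAsFactors = FALSE)
  df$rau <- 50 + 5 * (df$condition != "reverb") + rnorm(nrow(df), 0, 5)
  expect_error(fit_rt60_lmm(df), "rt60_50")
  th <- data.frame(subject = sprintf("S%02d", 1:12),
                   rt60_50 = seq(0.6, 1.4, length.out = 12))
  res <- fit_rt60_lmm(df, th)
  expect_setequal(rownames(res$anova),
                  c("condition", "rt60_50", "condition:rt60_50"))
})

test_that("ICC(3,1) matches a brute-force ANOVA decomposition and its edge cases", {
  fix_seed(70)
  test_v <- rnorm(40, 60, 10)
  retest <- test_v + rnorm(40, 0, 5)
  r <- icc3(test_v, retest)
  # independent oracle: two-way ANOVA mean squares via aov()
  d <- data.frame(y = c(test_v, retest),
                  subject = factor(rep(1:40, 2)),
                  occasion = factor(rep(1:2, each = 40)))
  ms <- summary(aov(y ~ subject + occasion, d))[[1]][, "Mean Sq"]
  icc_oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3])
  expect_equal(r$icc3, icc_oracle, tolerance = 1e-10)
  expect_gte(r$icc3, r$ci95[1]); expect_lte(r$icc3, r$ci95[2])
  # identical replicates: perfect reliability
  expect_equal(icc3(test_v, test_v)$icc3, 1, tolerance = 1e-12)
  # independent noise: near zero
  fix_seed(71)
  expect_lt(abs(icc3(rnorm(200), rnorm(200))$icc3), 0.15)
  expect_error(icc3(1:10, 1:9), "same length")
  expect_error(icc3(1:3, 1:3), "at least 5")
})

test_that("rating blocks flag degenerate zero-variance pairs and keep Bonferroni dominance", {
  listeners <- lapply(1:6, function(i)
    listener_profile(sprintf("S%02d", i), 0.68, 20, 0.02,
                     rng_seed = 100 + i, rt60_50 = 1))
  cs <- expand.grid(subject = sprintf("S%02d", 1:6),
                    condition = study_conditions(),
                    stringsAsFactors = FALSE)
  cs$stoi_mean <- 0.8                               # all conditions identical
  rb <- run_rating_block(listeners, cs, noise_sd = 0)
  expect_true(all(rb$tests$degenerate))
  expect_true(all(rb$tests$p == 1))
  expect_true(all(rb$ratings$score == 50))
  rb2 <- run_rating_block(listeners, cs, noise_sd = 5)
  expect_true(all(rb2$tests$p_bonferroni >= rb2$tests$p - 1e-12))
  bad <- rating_pairs(); bad$a[1] <- "mystery"
  expect_error(run_rating_block(listeners, cs, pairs = bad), "mystery")
})
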