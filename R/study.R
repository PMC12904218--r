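# Population mean of the listener s50 parameter (STOI at 50% words
# correct). Calibrated once against this package's own stimulus chain so
# that the median titrated RT60_50% of the default listener population
# lands at 1.0 s (scripts/calibrate_listeners.R reproduces the value).
S50_DEFAULT_MEAN <- 0.681

#' Synthetic listener profile
#'
#' A simulated CI listener is a three-parameter psychometric function on
#' the STOI axis: the probability of recognising a word at objective
#' intelligibility `s` is `p = (1 - lapse) * plogis(slope * (s - s50))`.
#'
#' @param subject_id Identifier.
#' @param s50 STOI at which 50% of words are recognised (0 < s50 < 1).
#' @param slope Logistic slope per STOI unit (> 0).
#' @param lapse Upper-asymptote shortfall in `[0, 0.1]`.
#' @param rng_seed Integer seed driving all of this listener's random
#'   behaviour.
#' @param rt60_50 Optional titrated RT60 at 50% words correct (seconds);
#'   filled in by [titrate_rt60_50()].
#' @return An object of class `listener_profile`.
#' @export
listener_profile <- function(subject_id, s50, slope, lapse = 0.02,
                             rng_seed = 1L, rt60_50 = NA_real_) {
  stopifnot(s50 > 0, s50 < 1, slope > 0, lapse >= 0, lapse <= 0.1)
  structure(list(subject_id = as.character(subject_id), s50 = s50,
                 slope = slope, lapse = lapse,
                 rng_seed = as.integer(rng_seed), rt60_50 = rt60_50),
            class = "listener_profile")
}

#' Draw a listener population
#'
#' Samples `n` listener profiles: `s50 ~ Normal(s50_mean, s50_sd)`
#' truncated to `s50_bounds`, `slope ~ Uniform(18, 28)`,
#' `lapse ~ Uniform(0, 0.05)`. The slope range is calibrated so that the
#' objective benefit of dereverberation in this package's stimulus chain
#' maps onto word-score gains of the size seen in CI listening studies. The default `s50_sd` and bounds keep every
#' listener's 50% operating point on or just beyond the 0.4-1.4 s
#' titration grid of the package's own stimulus chain (calibrated once;
#' see scripts/calibrate_listeners.R).
#'
#' @param n Number of listeners.
#' @param seed Population seed.
#' @param s50_mean,s50_sd Population mean and SD of `s50`.
#' @param slope_range,lapse_max Ranges of the remaining parameters.
#' @param s50_bounds Truncation interval for `s50`.
#' @return List of [listener_profile()] objects.
#' @export
sample_listeners <- function(n = 15, seed = 1L, s50_mean = S50_DEFAULT_MEAN,
                             s50_sd = 0.025, slope_range = c(18, 28),
                             lapse_max = 0.05, s50_bounds = c(0.646, 0.781)) {
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      s50 <- min(max(rnorm(1, s50_mean, s50_sd), s50_bounds[1]),
                 s50_bounds[2])
      listener_profile(
        subject_id = sprintf("S%02d", i), s50 = s50,
        slope = runif(1, slope_range[1], slope_range[2]),
        lapse = runif(1, 0, lapse_max),
        rng_seed = as.integer(seed * 1000L + i))
    })
  })
}

psychometric_p <- function(listener, stoi) {
  (1 - listener$lapse) * plogis(listener$slope * (stoi - listener$s50))
}

#' Simulate word-level scoring of one sentence
#'
#' @param listener A [listener_profile()].
#' @param stoi Objective intelligibility of the presented sentence.
#' @param n_words Words per sentence (binomial trials).
#' @return Number of words reported correctly (uses the current RNG
#'   stream; seed externally for reproducibility).
#' @export
simulate_word_scores <- function(listener, stoi, n_words = 5) {
  stopifnot(inherits(listener, "listener_profile"))
  rbinom(length(stoi), n_words, psychometric_p(listener, stoi))
}

#' Rationalized arcsine transform (RAU)
#'
#' Studebaker's rationalized arcsine units for `x` correct out of `n`:
#' `theta = asin(sqrt(x/(n+1))) + asin(sqrt((x+1)/(n+1)))`,
#' `RAU = (146/pi) * theta - 23`. Near-linear in percent over the
#' mid-range, stretched near 0 and 100% to stabilise the variance of
#' proportion scores.
#'
#' @param n_correct Correct count(s), `0 <= n_correct <= n_words`.
#' @param n_words Total words.
#' @return RAU value(s).
#' @export
rau_transform <- function(n_correct, n_words) {
  if (any(n_correct < 0) || any(n_correct > n_words))
    stop("n_correct must lie in [0, n_words]")
  theta <- asin(sqrt(n_correct / (n_words + 1))) +
    asin(sqrt((n_correct + 1) / (n_words + 1)))
  146 / pi * theta - 23
}

snap_to_grid <- function(x, step = 0.05) round(x / step) * step

#' STOI of unprocessed reverberant sentences over an RT60 grid
#'
#' Builds the objective-intelligibility table that the titration and
#' rating simulations consume: for each grid RT60, sentences are passed
#' through the concatenation protocol with the corresponding simulated
#' room response and scored against the clean originals.
#'
#' @param sentence_seeds Integer seeds of the sentence set.
#' @param grid RT60 values in seconds.
#' @param sample_rate Hz.
#' @param rir_seed Sign-stream seed for the room simulations.
#' @return Data frame with columns `rt60`, `seed`, `stoi`.
#' @export
reverb_stoi_table <- function(sentence_seeds, grid = seq(0.4, 1.4, by = 0.1),
                              sample_rate = 16000, rir_seed = 1L) {
  rows <- list()
  for (rt in grid) {
    spec <- room_spec_for_rt60(rt, sample_rate = sample_rate)
    ir <- simulate_rir(spec, seed = rir_seed)
    for (s in sentence_seeds) {
      sent <- generate_pseudo_sentence(s, sample_rate)
      trial <- apply_protocol(sent, ir, processor = "none")
      v <- compute_stoi(sent$samples, trial$audio, sample_rate)$value
      rows[[length(rows) + 1]] <- data.frame(rt60 = rt, seed = s, stoi = v)
    }
  }
  do.call(rbind, rows)
}

#' Titrate the RT60 at 50% word recognition
#'
#' Simulates the adaptive part of the listening session: at each grid RT60
#' the listener scores `sentences_per_rt60` sentences of
#' `n_words` words, and the RT60_50% is linearly interpolated between the
#' bracketing grid points of the first downward crossing of 50% correct.
#'
#' @param listener A [listener_profile()].
#' @param stoi_table Table from [reverb_stoi_table()] covering `grid`.
#' @param grid RT60 grid in seconds.
#' @param sentences_per_rt60 Sentences presented per grid point.
#' @param n_words Words per sentence.
#' @return A list of class `threshold_result`: `rt60_50`, `grid`,
#'   `percents`.
#' @export
titrate_rt60_50 <- function(listener, stoi_table,
                            grid = seq(0.4, 1.4, by = 0.1),
                            sentences_per_rt60 = 10, n_words = 5) {
  stopifnot(inherits(listener, "listener_profile"))
  percents <- with_local_seed(listener$rng_seed, {
    vapply(grid, function(rt) {
      sub <- stoi_table[abs(stoi_table$rt60 - rt) < 1e-9, ]
      if (nrow(sub) == 0)
        stop("stoi_table has no entries for RT60 = ", rt)
      seeds <- sub$seed[seq_len(min(sentences_per_rt60, nrow(sub)))]
      st <- sub$stoi[match(seeds, sub$seed)]
      100 * sum(simulate_word_scores(listener, st, n_words)) /
        (length(st) * n_words)
    }, numeric(1))
  })
  rt50 <- interpolate_crossing(grid, percents)
  structure(list(rt60_50 = rt50, grid = grid, percents = percents),
            class = "threshold_result")
}

# Locate the 50% point on a percent-vs-RT60 track: an exact grid hit wins;
# otherwise linear interpolation at the first downward crossing. A track
# that plainly heads through 50% just beyond the grid is linearly
# extrapolated from a fit to the outermost points, capped one grid step
# outside (clinical sessions of this design report thresholds slightly
# beyond their own titration grid). A track far from 50% is an error.
interpolate_crossing <- function(grid, percents) {
  hit <- which(abs(percents - 50) < 1e-9)
  if (length(hit) > 0) return(grid[hit[1]])
  n <- length(grid)
  cross <- which(percents[-n] > 50 & percents[-1] < 50)
  if (length(cross) > 0) {
    i <- cross[1]
    return(grid[i] + (percents[i] - 50) / (percents[i] - percents[i + 1]) *
             (grid[i + 1] - grid[i]))
  }
  step <- grid[n] - grid[n - 1]
  k <- min(4L, n)                      # outer points used for the trend fit
  trend <- function(sel) coef(lm(percents[sel] ~ grid[sel]))[[2]]
  slope_or_all <- function(sel) {
    sl <- trend(sel)
    if (sl < 0) sl else trend(seq_len(n))
  }
  if (min(percents) > 50) {            # still above 50 at the harshest RT60
    sl <- slope_or_all((n - k + 1):n)
    if (sl < 0) {
      rt <- grid[n] + (percents[n] - 50) / (-sl)
      return(min(rt, grid[n] + step))
    }
  } else if (max(percents) < 50) {     # already below 50 at the easiest RT60
    sl <- slope_or_all(1:k)
    if (sl < 0) {
      rt <- grid[1] - (50 - percents[1]) / (-sl)
      return(max(rt, grid[1]))
    }
  }
  stop(sprintf(
    "no downward 50%% crossing on or near the grid (percent range %.1f-%.1f)",
    min(percents), max(percents)))
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("RT60_50%% = %.3f s (grid %.2g-%.2g s)\n",
              x$rt60_50, min(x$grid), max(x$grid)))
  invisible(x)
}

# Compute STOI for all three conditions of one sentence in one pass
# (reverberant: the WPE output is reused by the post-filter; clean:
# the unprocessed condition is the identity and scores exactly 1).
process_sentence_conditions <- function(sentence, ir = NULL, rt60 = NA,
                                        stft = stft_config(),
                                        wpe = wpe_config()) {
  fs <- sentence$sample_rate
  len <- length(sentence$samples)
  concat <- rep(sentence$samples, 5)
  if (is.null(ir)) {
    x <- concat; dd <- 0L
  } else {
    x <- fft_convolve(concat, ir$samples)
    dd <- ir$direct_index - 1L
  }
  frames <- stft_analyze(x, stft)
  psd <- oracle_psd(stft_analyze(c(numeric(dd), concat,
                                   numeric(max(0, length(x) - dd - length(concat)))),
                                 stft))
  res <- wpe_dereverb(frames, wpe, psd)
  y_wpe <- stft_synthesize(res$frames)
  rt_pf <- if (is.null(ir)) 0.3 else rt60
  pf <- late_reverb_postfilter(res$frames, postfilter_config(rt_pf))
  y_wpepf <- stft_synthesize(pf)
  extract <- function(sig) sig[(3L * len + dd + 1):(3L * len + dd + len)]
  sc <- function(sig) compute_stoi(sentence$samples, extract(sig), fs)$value
  if (is.null(ir)) {
    c(clean = 1, clean_wpe = sc(y_wpe), clean_wpepf = sc(y_wpepf))
  } else {
    c(reverb = sc(x), reverb_wpe = sc(y_wpe), reverb_wpepf = sc(y_wpepf))
  }
}

# Environment-backed cache of per-(condition, rt60, sentence) STOI values.
new_stoi_cache <- function() new.env(parent = emptyenv())

cached_condition_stoi <- function(cache, sentence_seed, rt60 = NA,
                                  sample_rate = 16000, rir_seed = 1L,
                                  stft = stft_config(), wpe = wpe_config()) {
  key <- paste0("s", sentence_seed, "_rt",
                if (is.na(rt60)) "clean" else sprintf("%.3f", rt60))
  if (!is.null(cache[[key]])) return(cache[[key]])
  sent <- generate_pseudo_sentence(sentence_seed, sample_rate)
  ir <- NULL
  if (!is.na(rt60)) {
    ir_key <- sprintf("ir_%.3f", rt60)
    ir <- cache[[ir_key]]
    if (is.null(ir)) {
      spec <- room_spec_for_rt60(rt60, sample_rate = sample_rate)
      ir <- simulate_rir(spec, seed = rir_seed)
      cache[[ir_key]] <- ir
    }
  }
  v <- process_sentence_conditions(sent, ir, rt60, stft, wpe)
  cache[[key]] <- v
  v
}

#' Simulate the six-condition crossover intelligibility test
#'
#' For every listener, condition, and replicate (test/retest) a list of
#' sentences is scored word by word through the listener's psychometric
#' function applied to the objective intelligibility (STOI) of each
#' processed sentence. Reverberant conditions run at the listener's
#' titrated RT60_50%, snapped to the 0.05 s stimulus grid. Condition order
#' is randomized per listener and recorded (but, as in a crossover design
#' with randomized order, not modelled).
#'
#' @param listeners List of [listener_profile()]s, each with `rt60_50` set.
#' @param n_sentences Sentences per condition list.
#' @param n_words Words per sentence.
#' @param sentence_seeds Seeds of the sentence bank (defaults derive from
#'   `seed`); the same bank is shared across listeners and replicates, so
#'   test-retest variability comes from word-level response noise.
#' @param seed Study-level seed (sentence bank, room sign streams).
#' @param sample_rate Hz.
#' @param grid_step Stimulus RT60 grid resolution (s).
#' @param cache Optional STOI cache (from a previous call) to reuse.
#' @return Data frame of class `condition_scores`: one row per listener x
#'   condition x replicate with `n_correct`, `percent`, `rau`, the
#'   presentation `order`, and `rt60_used`; the per-listener mean condition
#'   STOI table is attached as attribute `condition_stoi`.
#' @export
run_crossover_study <- function(listeners, n_sentences = 20, n_words = 5,
                                sentence_seeds = NULL, seed = 1L,
                                sample_rate = 16000, grid_step = 0.05,
                                cache = NULL) {
  if (any(vapply(listeners, function(l) is.na(l$rt60_50), logical(1))))
    stop("every listener needs a titrated rt60_50 (run titrate_rt60_50 first)")
  if (is.null(sentence_seeds))
    sentence_seeds <- as.integer(seed) * 1000L + seq_len(n_sentences)
  if (is.null(cache)) cache <- new_stoi_cache()
  conds <- study_conditions()
  rows <- list()
  cond_stoi_rows <- list()
  for (l in listeners) {
    rt <- snap_to_grid(l$rt60_50, grid_step)
    stoi_by_cond <- sapply(conds, function(cond) numeric(0), simplify = FALSE)
    for (s in sentence_seeds) {
      cl <- cached_condition_stoi(cache, s, NA, sample_rate, rir_seed = seed)
      rv <- cached_condition_stoi(cache, s, rt, sample_rate, rir_seed = seed)
      for (cond in names(cl)) stoi_by_cond[[cond]] <- c(stoi_by_cond[[cond]], cl[[cond]])
      for (cond in names(rv)) stoi_by_cond[[cond]] <- c(stoi_by_cond[[cond]], rv[[cond]])
    }
    ord <- with_local_seed(l$rng_seed + 17L, sample(length(conds) * 2L))
    k <- 0L
    for (cond in conds) {
      for (repl in c("test", "retest")) {
        k <- k + 1L
        st <- stoi_by_cond[[cond]]
        nc <- with_local_seed(l$rng_seed + 100L * k, {
          sum(simulate_word_scores(l, st, n_words))
        })
        nw <- length(st) * n_words
        rows[[length(rows) + 1]] <- data.frame(
          subject = l$subject_id, condition = cond, replicate = repl,
          rt60_used = if (grepl("^reverb", cond)) rt else NA_real_,
          rt60_50 = l$rt60_50, n_words = nw, n_correct = nc,
          percent = 100 * nc / nw,
          rau = rau_transform(nc, nw), order = ord[k])
      }
      cond_stoi_rows[[length(cond_stoi_rows) + 1]] <- data.frame(
        subject = l$subject_id, condition = cond,
        stoi_mean = mean(stoi_by_cond[[cond]]))
    }
  }
  scores <- do.call(rbind, rows)
  scores$condition <- factor(scores$condition, levels = conds)
  attr(scores, "condition_stoi") <- do.call(rbind, cond_stoi_rows)
  class(scores) <- c("condition_scores", class(scores))
  scores
}

#' Mixed model of RAU scores across the six conditions
#'
#' Fits, by REML, `rau ~ condition + (1 | subject)` with independent
#' homoscedastic residuals (the scaled-identity covariance structure),
#' reports the omnibus condition F test (Satterthwaite degrees of
#' freedom), and all pairwise condition contrasts with Sidak-adjusted
#' p values (`p_adj = 1 - (1 - p)^m`).
#'
#' @param scores Data frame from [run_crossover_study()] (needs `rau`,
#'   `condition`, `subject`).
#' @return A list of class `lmm_result`: `fit`, `fixed` (estimates and
#'   SEs), `ranef_var`, `resid_var`, `omnibus` (F, df, p), `pairwise`
#'   (estimate, SE, df, t, p, p_sidak).
#' @export
fit_condition_lmm <- function(scores) {
  check_complete_design(scores)
  fit <- lmerTest::lmer(rau ~ condition + (1 | subject), data = scores,
                        REML = TRUE)
  an <- anova(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  emm <- emmeans::emmeans(fit, "condition")
  pw <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                              adjust = "none"))
  m <- nrow(pw)
  pw$p_sidak <- 1 - (1 - pw$p.value)^m
  structure(list(
    fit = fit,
    fixed = coef(summary(fit)),
    ranef_var = vc$vcov[vc$grp == "subject"],
    resid_var = vc$vcov[vc$grp == "Residual"],
    omnibus = list(F = an$`F value`[1], df1 = an$NumDF[1], df2 = an$DenDF[1],
                   p = an$`Pr(>F)`[1]),
    pairwise = data.frame(contrast = pw$contrast, estimate = pw$estimate,
                          se = pw$SE, df = pw$df, t = pw$t.ratio,
                          p = pw$p.value, p_sidak = pw$p_sidak)),
    class = "lmm_result")
}

check_complete_design <- function(scores) {
  need <- c("rau", "condition", "subject")
  if (!all(need %in% names(scores)))
    stop("scores must contain columns ", paste(need, collapse = ", "))
  tab <- table(scores$subject, scores$condition)
  if (any(tab == 0)) {
    miss <- which(tab == 0, arr.ind = TRUE)
    stop("design has empty cells: ",
         paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
               sep = ":", collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("Condition LMM: omnibus F(%g, %.1f) = %.2f, p = %.3g\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$F, x$omnibus$p))
  cat(sprintf("  subject intercept var %.2f, residual var %.2f\n",
              x$ranef_var, x$resid_var))
  print(x$pairwise, digits = 3)
  invisible(x)
}

#' Mixed model of reverberant-condition RAU scores against RT60_50%
#'
#' Restricts the data to the three reverberant conditions and fits
#' `rau ~ condition * rt60_50 + (1 | subject)` by REML, testing whether a
#' listener's operating point modulates the benefit of the algorithms.
#'
#' @param scores Data frame from [run_crossover_study()].
#' @param thresholds Optional data frame `subject`, `rt60_50`; defaults to
#'   the `rt60_50` column of `scores`.
#' @return A list of class `lmm_rt60_result`: `fit`, `anova` (F tests for
#'   condition, rt60_50 and their interaction).
#' @export
fit_rt60_lmm <- function(scores, thresholds = NULL) {
  sub <- scores[grepl("^reverb", as.character(scores$condition)), ,
                drop = FALSE]
  sub$condition <- droplevels(factor(sub$condition))
  if (!is.null(thresholds)) {
    sub$rt60_50 <- thresholds$rt60_50[match(sub$subject, thresholds$subject)]
  }
  if (!("rt60_50" %in% names(sub)) || any(is.na(sub$rt60_50)))
    stop("rt60_50 missing; supply thresholds")
  fit <- lmerTest::lmer(rau ~ condition * rt60_50 + (1 | subject),
                        data = sub, REML = TRUE)
  structure(list(fit = fit, anova = anova(fit)), class = "lmm_rt60_result")
}

#' @export
print.lmm_rt60_result <- function(x, ...) {
  print(x$anova, digits = 3)
  invisible(x)
}

#' The paired-comparison design of the preference ratings
#'
#' Four measurement pairs (does dereverberation help?) and four control
#' pairs (is clean speech altered? does an identical pair rate at
#' indifference?).
#'
#' @return Data frame with columns `pair`, `a`, `b`, `type`.
#' @export
rating_pairs <- function() {
  data.frame(
    pair = c("reverb_vs_clean", "reverb_vs_reverb_wpe",
             "reverb_vs_reverb_wpepf", "reverb_wpe_vs_reverb_wpepf",
             "clean_vs_clean_wpe", "clean_vs_clean_wpepf",
             "clean_wpe_vs_clean_wpepf", "reverb_vs_reverb"),
    a = c("reverb", "reverb", "reverb", "reverb_wpe",
          "clean", "clean", "clean_wpe", "reverb"),
    b = c("clean", "reverb_wpe", "reverb_wpepf", "reverb_wpepf",
          "clean_wpe", "clean_wpepf", "clean_wpepf", "reverb"),
    type = c(rep("measurement", 4), rep("control", 4)))
}

#' Simulate a block of paired preference ratings
#'
#' Each rating is a 0-100 slider with 50 = indifference. The simulated
#' listener's preference scales with the objective quality difference:
#' `score = 50 + 50 * tanh(gain * (STOI_b - STOI_a)) + noise`, clipped to
#' `[0, 100]`, so scores above 50 favour the second-listed member of the
#' pair; the saturating transfer mimics a bounded slider, where an obvious
#' quality gap pushes ratings towards the endpoint without pinning every
#' response exactly at it. Per pair, the test/retest means are compared against 50 with a
#' two-sided one-sample t test; p values are Bonferroni-corrected over the
#' pairs of the block. A zero-variance pair (all ratings identical) is
#' reported with `p = 1` and flagged `degenerate`.
#'
#' @param listeners List of [listener_profile()]s.
#' @param condition_stoi Data frame `subject`, `condition`, `stoi_mean`
#'   (attached to the result of [run_crossover_study()]).
#' @param pairs Pair design, a subset of [rating_pairs()].
#' @param outcome Label of the judged dimension (effort, naturalness,
#'   intelligibility); affects bookkeeping only, the simulated preference
#'   model is shared.
#' @param preference_gain Sensitivity of the saturating preference
#'   transfer (rating points per STOI difference near indifference is
#'   `50 * gain`); the default maps the typical algorithm benefit
#'   (~0.02 STOI) to roughly 11 rating points while a clean-vs-reverberant
#'   gap drives the slider close to its endpoint.
#' @param noise_sd Rating noise SD.
#' @return A list of class `rating_block`: `ratings` (one row per listener
#'   x pair x replicate) and `tests` (per-pair t table with `p_bonferroni`).
#' @export
run_rating_block <- function(listeners, condition_stoi,
                             pairs = rating_pairs(),
                             outcome = c("effort", "naturalness",
                                         "intelligibility"),
                             preference_gain = 12, noise_sd = 8) {
  outcome <- match.arg(outcome)
  bad <- setdiff(c(pairs$a, pairs$b), study_conditions())
  if (length(bad) > 0)
    stop("unknown condition label(s) in pairs: ", paste(bad, collapse = ", "))
  off <- match(outcome, c("effort", "naturalness", "intelligibility")) * 7919L
  rows <- list()
  for (l in listeners) {
    cs <- condition_stoi[condition_stoi$subject == l$subject_id, ]
    stoi_of <- function(cond) {
      v <- cs$stoi_mean[cs$condition == cond]
      if (length(v) != 1) stop("missing condition STOI for ", l$subject_id,
                               " / ", cond)
      v
    }
    r <- with_local_seed(l$rng_seed + off, {
      do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
        dv <- stoi_of(pairs$b[i]) - stoi_of(pairs$a[i])
        score <- 50 + 50 * tanh(preference_gain * dv) + rnorm(2, 0, noise_sd)
        data.frame(subject = l$subject_id, outcome = outcome,
                   pair = pairs$pair[i], type = pairs$type[i],
                   replicate = c("test", "retest"),
                   score = pmin(pmax(score, 0), 100))
      }))
    })
    rows[[length(rows) + 1]] <- r
  }
  ratings <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    sub <- ratings[ratings$pair == pairs$pair[i], ]
    means <- tapply(sub$score, sub$subject, mean)
    if (var(means) == 0) {
      data.frame(pair = pairs$pair[i], type = pairs$type[i],
                 mean = mean(means), t = NA_real_, df = length(means) - 1,
                 p = 1, degenerate = TRUE)
    } else {
      tt <- t.test(means, mu = 50)
      data.frame(pair = pairs$pair[i], type = pairs$type[i],
                 mean = mean(means), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 degenerate = FALSE)
    }
  }))
  tests$p_bonferroni <- pmin(1, nrow(pairs) * tests$p)
  structure(list(ratings = ratings, tests = tests), class = "rating_block")
}

#' @export
print.rating_block <- function(x, ...) {
  print(x$tests, digits = 3)
  invisible(x)
}

#' Intraclass correlation ICC(3,1) for test-retest data
#'
#' Two-way mixed-effects, consistency, single-measurement ICC:
#' `ICC(3,1) = (MS_between - MS_error) / (MS_between + (k - 1) MS_error)`
#' from the two-way (subject x rater) ANOVA decomposition, with the 95%
#' confidence interval from the F-distribution method.
#'
#' @param test,retest Paired measurement vectors (same subjects, k = 2
#'   occasions), length >= 5.
#' @param conf_level Confidence level for the interval.
#' @return A list of class `icc_result`: `icc3`, `ci95`, `ms_between`,
#'   `ms_error`.
#' @export
icc3 <- function(test, retest, conf_level = 0.95) {
  if (length(test) != length(retest))
    stop("test and retest must have the same length")
  n <- length(test)
  if (n < 5) stop("need at least 5 paired measurements")
  y <- cbind(test, retest)
  k <- 2
  grand <- mean(y)
  subj_means <- rowMeans(y)
  occ_means <- colMeans(y)
  ss_between <- k * sum((subj_means - grand)^2)
  ss_occ <- n * sum((occ_means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_error <- ss_total - ss_between - ss_occ
  ms_between <- ss_between / (n - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  icc <- (ms_between - ms_error) / (ms_between + (k - 1) * ms_error)
  f0 <- ms_between / ms_error
  alpha <- 1 - conf_level
  fl <- f0 / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- f0 * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  structure(list(icc3 = icc, ci95 = ci, ms_between = ms_between,
                 ms_error = ms_error),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f (95%% CI %.3f to %.3f)\n",
              x$icc3, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Run the full simulated listening study
#'
#' Convenience driver reproducing the whole session for a synthetic
#' listener panel: titration of each listener's RT60_50%, the
#' six-condition crossover intelligibility test with test/retest, both
#' mixed-model analyses, the three preference-rating blocks, and ICC(3,1)
#' test-retest reliability of the ratings.
#'
#' @param n_listeners Panel size.
#' @param seed Master seed.
#' @param n_sentences Sentences per condition list.
#' @param titration_sentences Sentences per titration grid point.
#' @param sample_rate Hz.
#' @return A list of class `study_result`: `listeners`, `thresholds`,
#'   `scores`, `lmm_condition`, `lmm_rt60`, `ratings` (per outcome),
#'   `icc`.
#' @export
simulate_study <- function(n_listeners = 15, seed = 1L, n_sentences = 20,
                           titration_sentences = 10, sample_rate = 16000) {
  listeners <- sample_listeners(n_listeners, seed = seed)
  tit_seeds <- as.integer(seed) * 1000L + 500L + seq_len(titration_sentences)
  tab <- reverb_stoi_table(tit_seeds, sample_rate = sample_rate,
                           rir_seed = seed)
  thresholds <- list()
  for (i in seq_along(listeners)) {
    th <- titrate_rt60_50(listeners[[i]], tab)
    listeners[[i]]$rt60_50 <- th$rt60_50
    thresholds[[i]] <- data.frame(subject = listeners[[i]]$subject_id,
                                  rt60_50 = th$rt60_50)
  }
  thresholds <- do.call(rbind, thresholds)
  scores <- run_crossover_study(listeners, n_sentences = n_sentences,
                                seed = seed, sample_rate = sample_rate)
  cond_stoi <- attr(scores, "condition_stoi")
  lmm1 <- fit_condition_lmm(scores)
  lmm2 <- fit_rt60_lmm(scores)
  outcomes <- c("effort", "naturalness", "intelligibility")
  ratings <- lapply(outcomes, function(oc)
    run_rating_block(listeners, cond_stoi, outcome = oc))
  names(ratings) <- outcomes
  all_ratings <- do.call(rbind, lapply(ratings, `[[`, "ratings"))
  key <- interaction(all_ratings$subject, all_ratings$outcome,
                     all_ratings$pair)
  tv <- tapply(all_ratings$score[all_ratings$replicate == "test"],
               droplevels(key[all_ratings$replicate == "test"]), mean)
  rv <- tapply(all_ratings$score[all_ratings$replicate == "retest"],
               droplevels(key[all_ratings$replicate == "retest"]), mean)
  icc <- icc3(as.numeric(tv), as.numeric(rv[names(tv)]))
  structure(list(listeners = listeners, thresholds = thresholds,
                 scores = scores, lmm_condition = lmm1, lmm_rt60 = lmm2,
                 ratings = ratings, icc = icc),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Simulated study: %d listeners, median RT60_50%% = %.2f s\n",
              length(x$listeners), stats::median(x$thresholds$rt60_50)))
  means <- tapply(x$scores$percent, x$scores$condition, mean)
  cat("Mean percent correct by condition:\n")
  print(round(means, 1))
  print(x$lmm_condition)
  print(x$icc)
  invisible(x)
}
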