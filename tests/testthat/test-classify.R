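# toy scaled dataset: s speakers x 5 vowels x r reps on two measures with
# vowel centroids sep standard deviations apart
toy_scaled <- function(n_speakers = 12, reps = 4, sep = 2, seed = 31) {
  set.seed(seed)
  centers <- cbind(c(-1, -0.5, 0, 0.5, 1), c(0.5, -0.5, 0.5, -0.5, 0)) * sep
  rownames(centers) <- c("bid", "bed", "bad", "bod", "bud")
  df <- expand.grid(speaker = sprintf("S%02d", 1:n_speakers),
                    vowel = rownames(centers), repetition = 1:reps,
                    stringsAsFactors = FALSE)
  df$token <- paste(df$speaker, df$vowel, df$repetition, sep = "_")
  df$K5_X <- centers[df$vowel, 1] + rnorm(nrow(df))
  df$K6_Y <- centers[df$vowel, 2] + rnorm(nrow(df))
  tibble::as_tibble(df)
}

test_that("within-speaker scaling has the definitional closed forms", {
  d <- tibble::tibble(speaker = c("A", "A", "A", "B", "B", "B"),
                      K5_X = c(1, 2, 3, 11, 12, 13))
  s <- scale_within_speaker(d, cols = "K5_X")
  expect_equal(s$K5_X, c(-1, 0, 1, -1, 0, 1))

  # per-speaker mean ~0, sd ~1 on arbitrary data
  set.seed(32)
  d2 <- tibble::tibble(speaker = rep(c("A", "B"), each = 50),
                       MCI = c(rnorm(50, 3, 2), rnorm(50, -5, 0.3)))
  s2 <- scale_within_speaker(d2, cols = "MCI")
  for (sp in c("A", "B")) {
    v <- s2$MCI[s2$speaker == sp]
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(sd(v) - 1), 1e-12)
  }

  # zero-variance measure becomes all zeros with a warning
  d3 <- tibble::tibble(speaker = rep("A", 4), TC = rep(2.5, 4))
  expect_warning(s3 <- scale_within_speaker(d3, cols = "TC"),
                 "zero within-speaker variance")
  expect_equal(s3$TC, rep(0, 4))

  # NaN values pass through and are ignored in the statistics
  d4 <- tibble::tibble(speaker = rep("A", 4), TC = c(1, 2, 3, NaN))
  s4 <- scale_within_speaker(d4, cols = "TC")
  expect_equal(s4$TC[1:3], c(-1, 0, 1))
  expect_true(is.nan(s4$TC[4]))
})

test_that("well-separated vowel clusters classify near perfectly", {
  d <- toy_scaled(sep = 10)
  res <- resampled_classification(d, c("K5_X", "K6_Y"), n_reps = 20,
                                  seed = 1)
  expect_gt(mean(res$runs$accuracy), 0.99)
  expect_equal(res$runs$accuracy, 1 - tapply(res$trials$error,
                                             res$trials$replicate, mean),
               ignore_attr = TRUE)
})

test_that("pure-noise measures sit at 5-class chance", {
  d <- toy_scaled(n_speakers = 20, sep = 0, seed = 33)  # no signal at all
  res <- resampled_classification(d, c("K5_X", "K6_Y"), n_reps = 100,
                                  seed = 2)
  accs <- res$runs$accuracy
  # binomial null oracle: the Monte-Carlo sd of chance accuracy is governed
  # by the finite token pool, which all replicates share
  mc_sd <- sqrt(0.2 * 0.8 / nrow(d))
  expect_lt(abs(mean(accs) - 0.2), 3 * mc_sd)
})

test_that("classification is deterministic and splits are disjoint", {
  d <- toy_scaled()
  a <- resampled_classification(d, c("K5_X", "K6_Y"), n_reps = 10, seed = 5)
  b <- resampled_classification(d, c("K5_X", "K6_Y"), n_reps = 10, seed = 5)
  expect_identical(a$runs$accuracy, b$runs$accuracy)

  splits <- tonguespace:::speaker_splits(d$speaker, 25, 0.75, seed = 5)
  all_spk <- sort(unique(d$speaker))
  for (tr in splits) {
    expect_length(tr, floor(0.75 * length(all_spk)))
    expect_length(intersect(tr, setdiff(all_spk, tr)), 0)
  }
})

test_that("accuracy is invariant to within-speaker affine distortions", {
  d <- toy_scaled(seed = 36)
  base <- resampled_classification(d, c("K5_X", "K6_Y"), n_reps = 10,
                                   seed = 3)
  # distort each speaker's raw measures by a speaker-specific affine map,
  # then re-scale within speakers: identical task
  d2 <- d
  for (sp in unique(d2$speaker)) {
    i <- d2$speaker == sp
    off <- rnorm(1, 0, 10); gain <- runif(1, 0.2, 5)
    d2$K5_X[i] <- gain * d2$K5_X[i] + off
    d2$K6_Y[i] <- gain * d2$K6_Y[i] - off
  }
  d2 <- scale_within_speaker(d2, cols = c("K5_X", "K6_Y"))
  d1 <- scale_within_speaker(d, cols = c("K5_X", "K6_Y"))
  r1 <- resampled_classification(d1, c("K5_X", "K6_Y"), n_reps = 10,
                                 seed = 3)
  r2 <- resampled_classification(d2, c("K5_X", "K6_Y"), n_reps = 10,
                                 seed = 3)
  expect_equal(r1$runs$accuracy, r2$runs$accuracy, tolerance = 1e-9)
})

test_that("the accuracy sweep covers 64 ranked combos with shared splits", {
  cohort <- generate_cohort(small_cohort_config())
  m <- measure_table(cohort$dataset)
  sc <- scale_within_speaker(m)
  sw <- sweep_accuracy(sc, n_reps = 8, seed = 4)
  expect_equal(nrow(sw), 64)
  expect_false(is.unsorted(rev(sw$accuracy)))
  reps <- attr(sw, "replicates")
  expect_equal(dim(reps), c(64, 8))
  # the designed discriminative pair family (dorsum X + height) leads
  expect_true(grepl("K[4567]_X|HV_X", sw$position[1]))
})

test_that("label permutation drops the best combo to chance", {
  cohort <- generate_cohort(small_cohort_config())
  m <- measure_table(cohort$dataset)
  sc <- scale_within_speaker(m)
  set.seed(44)
  sc$vowel <- sample(sc$vowel)
  res <- resampled_classification(sc, c("K5_X", "K6_Y"), n_reps = 40,
                                  seed = 6)
  accs <- res$runs$accuracy
  mc_sd <- sqrt(0.2 * 0.8 / nrow(sc))
  expect_lt(abs(mean(accs) - 0.2), 3 * mc_sd)
})

test_that("error-model recovery: null data gives null interactions", {
  tr <- simulate_trial_errors(8000, baseline = 0, sd_speaker = 0,
                              sd_replicate = 0, seed = 10)
  em <- fit_error_model(tr)
  expect_s3_class(em, "error_model")
  expect_true(all(em$cell_predictions$p_error > 0 &
                    em$cell_predictions$p_error < 1))
  # all non-intercept coefficients near zero (p = 0.5 everywhere)
  expect_lt(max(abs(em$coefficients[-1])), 0.35)
  expect_lt(abs(em$coefficients[1]), 0.2)
})

test_that("error-model recovery: an injected cell effect is estimated", {
  eff <- data.frame(term = "vowelbed:positionK5_X", delta = 1.0)
  tr <- simulate_trial_errors(20000, baseline = -1, effects = eff,
                              seed = 11)
  em <- fit_error_model(tr)
  expect_equal(unname(em$coefficients["vowelbed:positionK5_X"]), 1.0,
               tolerance = 0.2)
})

test_that("the ridge fallback fits separated data finitely", {
  # complete separation: every 'bid' trial is an error, glm would diverge
  tr <- simulate_trial_errors(2000, baseline = -20, seed = 12)
  tr$error[tr$vowel == "bid"] <- TRUE
  X <- stats::model.matrix(~ vowel, data = tr)
  beta <- tonguespace:::ridge_logit(X, as.numeric(tr$error), lambda = 1e-3)
  expect_true(all(is.finite(beta)))
  p <- stats::plogis(drop(X %*% beta))
  expect_gt(mean(p[tr$vowel == "bid"]), 0.95)
})
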