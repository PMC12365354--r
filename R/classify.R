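#' Z-score measures within each speaker
#'
#' Centres and scales every measure column to mean 0, sample sd 1 (n-1
#' denominator) inside each speaker, removing anatomical size and probe
#' placement offsets before cross-speaker statistics.  A measure with zero
#' within-speaker variance is emitted as all zeros with a warning.
#' Non-finite values (flat-contour TC) are ignored in the statistics and
#' passed through unchanged.
#'
#' @param data a data frame with a `speaker` column.
#' @param cols measure columns to scale (default: the canonical 16 present).
#' @return `data` with the selected columns scaled.
#' @export
scale_within_speaker <- function(data, cols = NULL) {
  stopifnot("speaker" %in% names(data))
  if (is.null(cols)) cols <- intersect(measure_names()$all, names(data))
  flagged <- character(0)
  for (v in cols) {
    split_idx <- split(seq_len(nrow(data)), data$speaker)
    for (s in names(split_idx)) {
      i <- split_idx[[s]]
      vals <- data[[v]][i]
      fin <- is.finite(vals)
      sdv <- stats::sd(vals[fin])
      if (!is.finite(sdv) || sdv == 0) {
        vals[fin] <- 0
        flagged <- c(flagged, paste0(s, ":", v))
      } else {
        vals[fin] <- (vals[fin] - mean(vals[fin])) / sdv
      }
      data[[v]][i] <- vals
    }
  }
  if (length(flagged))
    warning("zero within-speaker variance, emitted as zeros: ",
            paste(flagged, collapse = ", "), call. = FALSE)
  data
}

# deterministic train/test speaker splits shared across combos (common
# random numbers, so combo rankings are not split-noise artifacts)
speaker_splits <- function(speakers, n_reps, train_fraction, seed) {
  speakers <- sort(unique(speakers))
  n_train <- floor(train_fraction * length(speakers))
  if (n_train < 1 || n_train >= length(speakers))
    stop("train_fraction leaves an empty train or test set")
  with_seed(seed, lapply(seq_len(n_reps), function(i)
    sort(sample(speakers, n_train))))
}

#' Speaker-held-out vowel classification for one measure pair
#'
#' For each replicate, a random 75% of speakers (without replacement) form
#' the training set; a linear discriminant classifier (empirical class
#' priors) is fit on the two within-speaker-scaled measures and evaluated
#' on all tokens of the held-out speakers.  Accuracy is the fraction of
#' correctly classified test tokens, pooled within a replicate.
#'
#' @param measures_scaled a measure table already passed through
#'   [scale_within_speaker()], with columns `speaker`, `token`, `vowel`.
#' @param combo character pair: one position measure, one height/shape
#'   measure.
#' @param n_reps number of resampling replicates (default 100).
#' @param train_fraction fraction of speakers used for training.
#' @param seed integer seed; the same seed reproduces the identical split
#'   sequence (and is shared across combos by [sweep_accuracy()]).
#' @param splits optionally, a precomputed split list from the internal
#'   split generator (used by [sweep_accuracy()]).
#' @param keep_trials record per-trial predictions (default TRUE).
#' @return List with `runs` (tibble: replicate, accuracy, n_test) and
#'   `trials` (tibble of per-token outcomes, if kept).
#' @export
resampled_classification <- function(measures_scaled, combo, n_reps = 100L,
                                     train_fraction = 0.75, seed = 1L,
                                     splits = NULL, keep_trials = TRUE) {
  stopifnot(length(combo) == 2L, all(combo %in% names(measures_scaled)))
  df <- measures_scaled[, c("speaker", "token", "vowel", combo)]
  names(df)[4:5] <- c("m1", "m2")
  df <- df[is.finite(df$m1) & is.finite(df$m2), ]
  df$vowel <- factor(df$vowel)
  if (is.null(splits))
    splits <- speaker_splits(df$speaker, n_reps, train_fraction, seed)
  runs <- vector("list", length(splits))
  trials <- if (keep_trials) vector("list", length(splits)) else NULL
  all_spk <- sort(unique(df$speaker))
  for (r in seq_along(splits)) {
    train_spk <- splits[[r]]
    redraw <- 0L
    repeat {
      train <- df[df$speaker %in% train_spk, ]
      test <- df[!(df$speaker %in% train_spk), ]
      if (nlevels(droplevels(train$vowel)) == nlevels(df$vowel) &&
          nrow(test) > 0L) break
      redraw <- redraw + 1L
      if (redraw > 10L)
        stop("replicate ", r, ": a training class stayed absent after 10 redraws")
      message("replicate ", r, ": training class absent, redrawing split")
      train_spk <- with_seed(seed * 1000L + r * 13L + redraw,
                             sort(sample(all_spk, length(train_spk))))
    }
    fit <- MASS::lda(vowel ~ m1 + m2, data = train)
    pred <- stats::predict(fit, test)$class
    err <- pred != test$vowel
    runs[[r]] <- tibble::tibble(replicate = r,
                                accuracy = 1 - mean(err),
                                n_test = nrow(test))
    if (keep_trials)
      trials[[r]] <- tibble::tibble(replicate = r, speaker = test$speaker,
                                    token = test$token,
                                    vowel = as.character(test$vowel),
                                    predicted = as.character(pred),
                                    error = as.logical(err))
  }
  list(runs = dplyr::bind_rows(runs),
       trials = if (keep_trials) dplyr::bind_rows(trials) else NULL)
}

#' Classification accuracy sweep over all 64 measure pairs
#'
#' Runs [resampled_classification()] for every position-by-height/shape
#' pair, reusing the same speaker-split sequence across pairs, and ranks
#' pairs by mean accuracy.
#'
#' @inheritParams resampled_classification
#' @param combos measure pairs (default: all 64).
#' @param keep_trials record per-trial outcomes for every combo (needed by
#'   the error model; default FALSE to save memory).
#' @return A tibble `position`, `height_shape`, `accuracy` (mean over
#'   replicates), sorted descending; per-replicate accuracies in attribute
#'   `replicates`, pooled trials (if kept) in attribute `trials`.
#' @export
sweep_accuracy <- function(measures_scaled, n_reps = 100L,
                           train_fraction = 0.75, seed = 1L,
                           combos = measure_combos(), keep_trials = FALSE) {
  splits <- speaker_splits(measures_scaled$speaker, n_reps,
                           train_fraction, seed)
  acc <- matrix(NA_real_, nrow(combos), n_reps)
  trials <- if (keep_trials) vector("list", nrow(combos)) else NULL
  for (i in seq_len(nrow(combos))) {
    cmb <- c(combos$position[i], combos$height_shape[i])
    res <- resampled_classification(measures_scaled, cmb, seed = seed,
                                    splits = splits,
                                    keep_trials = keep_trials)
    acc[i, ] <- res$runs$accuracy
    if (keep_trials) {
      res$trials$position <- cmb[1]
      res$trials$height_shape <- cmb[2]
      trials[[i]] <- res$trials
    }
  }
  out <- combos
  out$accuracy <- rowMeans(acc)
  ord <- order(out$accuracy, decreasing = TRUE)
  out <- out[ord, ]
  attr(out, "replicates") <- acc[ord, , drop = FALSE]
  if (keep_trials) attr(out, "trials") <- dplyr::bind_rows(trials)
  out
}

#' Mixed-logistic model of classification errors
#'
#' Fits a Bernoulli mixed-effects logistic regression predicting the
#' probability of a misclassification from the interaction of vowel with
#' the position measure and of vowel with the height/shape measure, with
#' random intercepts for speaker and for resampling replicate.  On
#' convergence failure or complete separation the model falls back to a
#' weakly ridge-penalised fixed-effects logistic fit (lambda = 1e-3), with
#' a notice.
#'
#' @param trials a trial table with columns `error` (logical), `vowel`,
#'   `position`, `height_shape`, `speaker`, `replicate`.
#' @return An object of class `error_model`: list with `coefficients`
#'   (fixed effects, log-odds), `ranef_variance` (speaker, replicate),
#'   `cell_predictions` (predicted error probability per vowel x position x
#'   height/shape cell, fixed effects only) and `method`.
#' @export
fit_error_model <- function(trials) {
  need <- c("error", "vowel", "position", "height_shape", "speaker",
            "replicate")
  stopifnot(all(need %in% names(trials)))
  df <- trials
  df$vowel <- factor(df$vowel)
  df$position <- factor(df$position)
  df$height_shape <- factor(df$height_shape)
  df$error <- as.numeric(df$error)
  fit <- tryCatch(
    lme4::glmer(error ~ vowel * position + vowel * height_shape +
                  (1 | speaker) + (1 | replicate),
                data = df, family = stats::binomial(), nAGQ = 0L,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    beta <- lme4::fixef(fit)
    vc <- lme4::VarCorr(fit)
    rv <- c(speaker = unname(vc$speaker[1]),
            replicate = unname(vc$replicate[1]))
    method <- "glmer"
  } else {
    message("mixed model did not converge; falling back to ridge-penalised ",
            "logistic regression (lambda = 1e-3)")
    X <- stats::model.matrix(~ vowel * position + vowel * height_shape,
                             data = df)
    beta <- ridge_logit(X, df$error, lambda = 1e-3)
    rv <- c(speaker = NA_real_, replicate = NA_real_)
    method <- "ridge"
  }
  grid <- expand.grid(vowel = levels(df$vowel),
                      position = levels(df$position),
                      height_shape = levels(df$height_shape),
                      KEEP.OUT.ATTRS = FALSE)
  Xg <- stats::model.matrix(~ vowel * position + vowel * height_shape,
                            data = grid)
  eta <- drop(Xg[, names(beta), drop = FALSE] %*% beta)
  grid$p_error <- stats::plogis(eta)
  structure(list(coefficients = beta, ranef_variance = rv,
                 cell_predictions = tibble::as_tibble(grid),
                 method = method),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model>", x$method, "fit,", length(x$coefficients),
      "fixed effects\n")
  invisible(x)
}

# plain IRLS logistic regression with an L2 penalty on all but the intercept
ridge_logit <- function(X, y, lambda = 1e-3, maxit = 100L, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(rep(lambda, p)); pen[1, 1] <- 0
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  names(beta) <- colnames(X)
  beta
}

#' Simulate classification-error trials with known cell effects
#'
#' Generates Bernoulli error outcomes on a vowel x position-measure x
#' height/shape-measure grid under a logistic model with speaker and
#' replicate random intercepts, for validating [fit_error_model()]
#' parameter recovery.
#'
#' @param n_trials total number of trials.
#' @param vowels,positions,height_shapes factor levels of the design.
#' @param baseline baseline log-odds of an error.
#' @param effects optional data frame `term`, `delta` adding `delta`
#'   log-odds whenever the named model-matrix term is active.
#' @param sd_speaker,sd_replicate random-intercept standard deviations.
#' @param n_speakers,n_replicates grouping-factor sizes.
#' @param seed integer seed.
#' @return A trial tibble suitable for [fit_error_model()], with the true
#'   linear predictor in `eta`.
#' @export
simulate_trial_errors <- function(n_trials, vowels = VOWELS_DEFAULT,
                                  positions = c("K4_X", "K5_X"),
                                  height_shapes = c("K6_Y", "TC"),
                                  baseline = -0.5, effects = NULL,
                                  sd_speaker = 0.3, sd_replicate = 0.2,
                                  n_speakers = 40L, n_replicates = 100L,
                                  seed = 1L) {
  with_seed(seed, {
    df <- tibble::tibble(
      vowel = factor(sample(vowels, n_trials, replace = TRUE),
                     levels = vowels),
      position = factor(sample(positions, n_trials, replace = TRUE),
                        levels = positions),
      height_shape = factor(sample(height_shapes, n_trials, replace = TRUE),
                            levels = height_shapes),
      speaker = sample(paste0("S", seq_len(n_speakers)), n_trials,
                       replace = TRUE),
      replicate = sample(seq_len(n_replicates), n_trials, replace = TRUE))
    u_spk <- stats::rnorm(n_speakers, 0, sd_speaker)
    names(u_spk) <- paste0("S", seq_len(n_speakers))
    u_rep <- stats::rnorm(n_replicates, 0, sd_replicate)
    X <- stats::model.matrix(~ vowel * position + vowel * height_shape,
                             data = df)
    eta <- baseline + u_spk[df$speaker] + u_rep[df$replicate]
    if (!is.null(effects))
      for (i in seq_len(nrow(effects))) {
        if (!(effects$term[i] %in% colnames(X)))
          stop("unknown design term: ", effects$term[i])
        eta <- eta + effects$delta[i] * X[, effects$term[i]]
      }
    df$eta <- unname(eta)
    df$error <- stats::runif(n_trials) < stats::plogis(df$eta)
    df$token <- paste0("t", seq_len(n_trials))
    df
  })
}
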