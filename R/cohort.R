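# fixed arc fractions of the 11 knots: nine equally spaced landmarks over
# the tongue surface plus two extra anterior knots in the tip/blade region
KNOT_FRACTIONS <- c(0, 0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875,
                    11 / 12, 23 / 24, 1)

#' Configuration of the synthetic articulatory cohort
#'
#' The generator emulates a vowel-production study: each speaker produces
#' several repetitions of five lax vowels, each token a midsagittal tongue
#' contour sampled at the 11 canonical knots.  The latent model places a
#' Gaussian constriction bump of height `degree_mm` at angle `theta_c`
#' (radians along a reference arc; small = anterior, large = posterior) on
#' a circular tongue-body arc, shears the posterior third by the root
#' advancement, and shifts the tongue body anteriorly for front vowels
#' (shift weight peaking over the dorsum, with root and tip relatively
#' anchored).  Speaker anatomy (uniform scale, translation, per-token probe
#' rotation jitter) and per-knot Gaussian landmark noise are layered on
#' top; posterior and tip knots receive proportionally more noise,
#' mirroring the poorer image quality near the hyoid shadow and the
#' sublingual airspace.  Formants follow linear models,
#' F2 = b0 - b1 * theta_c + noise (frontness raises F2) and
#' F1 = g0 - g1 * apex_height + noise (height lowers F1).
#'
#' @param n_speakers number of speakers (default 40).
#' @param vowels data frame with columns `label`, `theta_c` (strictly
#'   increasing from the most anterior to the most posterior vowel),
#'   `degree_mm`, `advance_mm`.
#' @param reps_per_vowel integer range of repetitions per speaker-vowel.
#' @param scale_range,translation_range_mm,rotation_jitter_sd_deg speaker
#'   anatomy parameters.
#' @param noise_sd_mm per-coordinate landmark noise (default 0.5 mm).
#' @param knot_noise_mult length-11 per-knot noise multipliers.
#' @param target_sd per-speaker idiolectal jitter of the vowel targets:
#'   named numeric `theta`, `degree`, `advance`.
#' @param token_sd per-token target jitter: named numeric `theta`,
#'   `degree`.
#' @param f2_model,f1_model named numerics `intercept`, `slope`, `noise_sd`
#'   for the formant couplings (Hz; slopes per radian and per mm).
#' @param seed integer seed; the whole cohort is a pure function of the
#'   configuration including the seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_speakers = 40L,
                          vowels = default_vowel_targets(),
                          reps_per_vowel = c(4L, 6L),
                          scale_range = c(0.85, 1.15),
                          translation_range_mm = c(-8, 8),
                          rotation_jitter_sd_deg = 2,
                          noise_sd_mm = 0.5,
                          knot_noise_mult = c(1.6, 1.6, 1.4, 1.1, 1, 1, 1,
                                              1, 1.1, 1.25, 1.4),
                          target_sd = c(theta = 0.20, degree = 1.3,
                                        advance = 0.7),
                          token_sd = c(theta = 0.05, degree = 0.4),
                          f2_model = c(intercept = 2550, slope = 600,
                                       noise_sd = 60),
                          f1_model = c(intercept = 1150, slope = 16,
                                       noise_sd = 40),
                          seed = 1L) {
  cfg <- list(n_speakers = as.integer(n_speakers),
              vowels = tibble::as_tibble(vowels),
              reps_per_vowel = as.integer(reps_per_vowel),
              scale_range = scale_range,
              translation_range_mm = translation_range_mm,
              rotation_jitter_sd_deg = rotation_jitter_sd_deg,
              noise_sd_mm = noise_sd_mm,
              knot_noise_mult = knot_noise_mult,
              target_sd = target_sd, token_sd = token_sd,
              f2_model = f2_model, f1_model = f1_model,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_vowel_targets <- function() {
  tibble::tibble(
    label      = c("bid", "bed", "bad", "bud", "bod"),
    theta_c    = c(0.80, 1.10, 1.45, 1.85, 2.30),
    degree_mm  = c(8.0, 5.0, 2.0, 4.0, 3.0),
    advance_mm = c(3.0, 1.5, 0.0, -0.5, -1.5))
}

validate_cohort_config <- function(cfg) {
  v <- cfg$vowels
  stopifnot(all(c("label", "theta_c", "degree_mm", "advance_mm") %in%
                  names(v)))
  if (cfg$n_speakers < 1L) stop("n_speakers must be positive")
  if (any(cfg$reps_per_vowel < 1L) ||
      cfg$reps_per_vowel[1] > cfg$reps_per_vowel[2])
    stop("reps_per_vowel must be a valid positive range")
  if (any(diff(v$theta_c) <= 0))
    stop("vowel theta_c must be strictly increasing (anterior to posterior)")
  if (any(v$theta_c < 0 | v$theta_c > pi))
    stop("theta_c must lie in [0, pi]")
  sds <- c(cfg$rotation_jitter_sd_deg, cfg$noise_sd_mm, cfg$target_sd,
           cfg$token_sd, cfg$f1_model["noise_sd"], cfg$f2_model["noise_sd"])
  if (any(sds < 0)) stop("all standard deviations must be non-negative")
  if (length(cfg$knot_noise_mult) != 11L || any(cfg$knot_noise_mult < 0))
    stop("knot_noise_mult must be 11 non-negative multipliers")
  invisible(cfg)
}

# template tongue-surface model in speaker-neutral space -------------------
# angle runs phi_post (posterior, vallecula) down to phi_ant (anterior, tip)
COHORT_GEOM <- list(radius = 40, phi_post = 2.95, phi_ant = 0.20,
                    bump_width = 0.35, shift_gain = 6, theta_mid = 1.55,
                    shift_center = 0.55, shift_width = 0.28,
                    advance_extent = 1 / 3)

# contour point at arc fraction f for latent parameters (template space)
template_surface <- function(f, theta, degree, advance) {
  g <- COHORT_GEOM
  phi <- g$phi_post + f * (g$phi_ant - g$phi_post)
  r <- g$radius + degree * exp(-(phi - theta)^2 / (2 * g$bump_width^2))
  x <- r * cos(phi)
  y <- r * sin(phi)
  # root advancement: shear the posterior third forward
  x <- x + advance * pmax(0, 1 - f / g$advance_extent)
  # tongue-body carriage: front vowels shift the dorsum anteriorly
  shift <- g$shift_gain * (g$theta_mid - theta)
  x <- x + shift * exp(-(f - g$shift_center)^2 / (2 * g$shift_width^2))
  cbind(x = x, y = y)
}

# maximal height of the noiseless template contour (the F1 latent)
template_apex_height <- function(theta, degree, advance) {
  f <- seq(0, 1, length.out = 200)
  max(template_surface(f, theta, degree, advance)[, 2])
}

#' Generate a synthetic articulatory cohort
#'
#' @param config a [cohort_config()].
#' @return List with `dataset` (a [tongue_dataset()] of contours and
#'   formants) and `truth` (tibble of the per-token latents: theta, degree,
#'   advance, apex height, speaker anatomy).  The output is a deterministic
#'   function of the configuration.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  g <- COHORT_GEOM
  with_seed(config$seed, {
    contours <- list()
    truth <- list()
    formants <- list()
    for (s in seq_len(config$n_speakers)) {
      spk <- sprintf("S%02d", s)
      sc <- stats::runif(1, config$scale_range[1], config$scale_range[2])
      tr <- stats::runif(2, config$translation_range_mm[1],
                         config$translation_range_mm[2])
      # idiolectal vowel targets
      tg <- config$vowels
      tg$theta_c <- tg$theta_c +
        stats::rnorm(nrow(tg), 0, config$target_sd["theta"])
      tg$degree_mm <- tg$degree_mm +
        stats::rnorm(nrow(tg), 0, config$target_sd["degree"])
      tg$advance_mm <- tg$advance_mm +
        stats::rnorm(nrow(tg), 0, config$target_sd["advance"])
      for (v in seq_len(nrow(tg))) {
        n_rep <- if (config$reps_per_vowel[1] == config$reps_per_vowel[2])
          config$reps_per_vowel[1]
        else sample(config$reps_per_vowel[1]:config$reps_per_vowel[2], 1)
        for (rep in seq_len(n_rep)) {
          theta <- tg$theta_c[v] +
            stats::rnorm(1, 0, config$token_sd["theta"])
          degree <- tg$degree_mm[v] +
            stats::rnorm(1, 0, config$token_sd["degree"])
          advance <- tg$advance_mm[v]
          kn <- template_surface(KNOT_FRACTIONS, theta, degree, advance)
          apex <- template_apex_height(theta, degree, advance)
          # anatomy: scale, per-token probe jitter, translation
          ang <- stats::rnorm(1, 0, config$rotation_jitter_sd_deg * pi / 180)
          R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
          kn <- sc * kn %*% t(R)
          kn <- sweep(kn, 2, tr, `+`)
          kn <- kn + stats::rnorm(22, 0, config$noise_sd_mm) *
            config$knot_noise_mult
          tok <- sprintf("%s_%s_%d", spk, tg$label[v], rep)
          contours[[tok]] <- knot_contour(spk, tok, tg$label[v], rep, kn,
                                          rotated = TRUE)
          f2 <- config$f2_model["intercept"] -
            config$f2_model["slope"] * theta +
            stats::rnorm(1, 0, config$f2_model["noise_sd"])
          f1 <- config$f1_model["intercept"] -
            config$f1_model["slope"] * apex +
            stats::rnorm(1, 0, config$f1_model["noise_sd"])
          f1 <- max(f1, 150)
          f2 <- max(f2, f1 + 200)
          formants[[tok]] <- tibble::tibble(speaker = spk, token = tok,
                                            f1_hz = unname(f1),
                                            f2_hz = unname(f2))
          truth[[tok]] <- tibble::tibble(
            speaker = spk, token = tok, vowel = tg$label[v],
            repetition = rep, theta = theta, degree = degree,
            advance = advance, apex_height = apex, scale = sc,
            trans_x = tr[1], trans_y = tr[2], probe_angle = ang)
        }
      }
    }
    names(contours) <- NULL
    list(dataset = tongue_dataset(contours, dplyr::bind_rows(formants)),
         truth = dplyr::bind_rows(truth))
  })
}

#' Analytic reference fixtures
#'
#' Small closed-form contours used throughout the test suite, each carrying
#' its expected measure values: a straight line (zero curvature), a unit
#' semicircle (total turning pi), circular arcs of given subtended angle, a
#' quarter-circle joined to a straight segment (turning pi/2; the junction
#' knot is flanked by close neighbours, mirroring the crowded tip/blade
#' knot spacing), a triangular tent with apex (4, 3) over chord (0,0)-(10,0)
#' (TCP = 0.3, TC = 2/3), and a two-bump contour whose higher bump is the
#' designed highest point.
#'
#' @return A named list of fixtures; each has `knots` (11 x 2), usually
#'   `points` (a dense analytic sampling), and `expected` (named list).
#' @export
reference_fixtures <- function() {
  arc_knots <- function(angle, radius = 10, n = 11) {
    th <- seq(pi / 2 + angle / 2, pi / 2 - angle / 2, length.out = n)
    cbind(x = radius * cos(th), y = radius * sin(th))
  }
  line <- list(
    knots = cbind(x = seq(0, 10, length.out = 11), y = rep(0, 11)),
    expected = list(mci = 0, tcp = 0, tc = NaN))
  semicircle <- list(
    knots = arc_knots(pi, radius = 1),
    points = {
      th <- seq(pi, 0, length.out = 500)
      cbind(x = cos(th), y = sin(th))
    },
    expected = list(mci = pi, hp = c(x = 0, y = 1)))
  make_arc <- function(angle) list(knots = arc_knots(angle),
                                   expected = list(mci = angle))
  qseg <- {
    s_arc <- pi / 2
    s_all <- c(seq(0, 1.40, length.out = 5), 1.52, s_arc, 1.62,
               seq(1.9, s_arc + 1, length.out = 3))
    pt <- function(s) if (s <= s_arc) c(sin(s), cos(s)) else c(1, -(s - s_arc))
    kn <- t(vapply(s_all, pt, numeric(2)))
    colnames(kn) <- c("x", "y")
    dense_s <- seq(0, s_arc + 1, length.out = 10000)
    dp <- t(vapply(dense_s, pt, numeric(2)))
    colnames(dp) <- c("x", "y")
    list(knots = kn, points = dp, expected = list(mci = pi / 2))
  }
  triangle <- {
    # tent sampled along both edges with the apex included exactly
    up <- cbind(seq(0, 4, length.out = 41), seq(0, 3, length.out = 41))
    dn <- cbind(seq(4, 10, length.out = 61), seq(3, 0, length.out = 61))
    pts <- rbind(up, dn[-1, ])
    colnames(pts) <- c("x", "y")
    k_up <- cbind(seq(0, 4, length.out = 5), seq(0, 3, length.out = 5))
    k_dn <- cbind(seq(4, 10, length.out = 7), seq(3, 0, length.out = 7))
    kn <- rbind(k_up, k_dn[-1, ])
    colnames(kn) <- c("x", "y")
    list(knots = kn, points = pts,
         expected = list(tcp = 0.3, tc = 2 / 3, hv = c(x = 4, y = 3),
                         d = c(x = 4, y = 0), ab = 10, ad = 4, db = 6,
                         hvd = 3))
  }
  two_bump <- {
    tt <- seq(0, 1, length.out = 11)
    y <- 3 * exp(-(tt - 0.3)^2 / (2 * 0.08^2)) +
      5 * exp(-(tt - 0.7)^2 / (2 * 0.08^2))
    list(knots = cbind(x = 30 * tt, y = y),
         expected = list(apex_near_x = 30 * 0.7))
  }
  list(line = line, semicircle = semicircle,
       arc_pi_6 = make_arc(pi / 6), arc_pi_2 = make_arc(pi / 2),
       arc_pi = make_arc(pi),
       quarter_segment = qseg, triangle = triangle, two_bump = two_bump)
}
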