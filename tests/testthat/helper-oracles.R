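# Independent oracles and small generators used across the suite.

# total absolute turning of a polyline: sum of absolute exterior angle
# changes between consecutive segments (independent of the package's
# finite-difference curvature integral)
oracle_turning <- function(points) {
  dx <- diff(points[, 1]); dy <- diff(points[, 2])
  ang <- atan2(dy, dx)
  d <- diff(ang)
  d <- (d + pi) %% (2 * pi) - pi   # wrap to (-pi, pi]
  sum(abs(d))
}

# brute-force Procrustes: golden-section search over rotation angle (both
# reflection branches), scale and translation solved by linear least
# squares at each angle; symmetric normalisation applied first
oracle_procrustes_ss <- function(source, target, symmetric = TRUE) {
  X <- as.matrix(target); Y <- as.matrix(source)
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  if (symmetric) {
    X <- X / sqrt(sum(X^2)); Y <- Y / sqrt(sum(Y^2))
  }
  ss_at <- function(a, flip) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    Yr <- Y %*% t(R)
    if (flip) Yr[, 2] <- -Yr[, 2]
    s <- sum(Yr * X) / sum(Yr^2)      # optimal scale, centred data
    sum((X - s * Yr)^2)
  }
  best <- Inf
  for (flip in c(FALSE, TRUE)) {
    grid <- seq(0, 2 * pi, length.out = 721)
    vals <- vapply(grid, ss_at, numeric(1), flip = flip)
    i <- which.min(vals)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(ss_at, c(lo, hi), flip = flip, tol = 1e-12)
    best <- min(best, opt$objective)
  }
  best
}

# random smooth single-bump contour: arc plus Gaussian bump, 11 knots
random_contour_knots <- function(radius = 40, bump = NULL, center = NULL,
                                 width = 0.35) {
  if (is.null(bump)) bump <- stats::runif(1, 2, 8)
  if (is.null(center)) center <- stats::runif(1, 0.9, 2.2)
  phi <- seq(2.9, 0.25, length.out = 11)
  r <- radius + bump * exp(-(phi - center)^2 / (2 * width^2))
  cbind(x = r * cos(phi), y = r * sin(phi))
}

# random similarity transform of a point matrix
random_similarity <- function(points, angle = stats::runif(1, 0, 2 * pi),
                              s = stats::runif(1, 0.5, 2),
                              tr = stats::rnorm(2, 0, 20)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(s * points %*% t(R), 2, tr, `+`)
}

# tiny long-format contour CSV for reader tests
write_long_fixture <- function(path, tokens = 2, knots = 11,
                               mutate = identity) {
  rows <- do.call(rbind, lapply(seq_len(tokens), function(i) {
    data.frame(speaker = "S01", token = paste0("tok", i), vowel = "bid",
               repetition = i, knot = seq_len(knots),
               x = seq(0, 50, length.out = knots),
               y = 30 + sin(seq(0, pi, length.out = knots)) * 10)
  }))
  rows <- mutate(rows)
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

# small deterministic cohort for fast end-to-end tests
small_cohort_config <- function(seed = 11, n_speakers = 8) {
  cohort_config(n_speakers = n_speakers, reps_per_vowel = c(4L, 4L),
                seed = seed)
}
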