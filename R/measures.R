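#' Densify a knot contour with an interpolating cubic spline
#'
#' x(t) and y(t) are interpolated independently by piecewise cubic
#' polynomials (Forsythe-Malcolm-Moler end conditions) against a shared
#' monotone parameter t, the cumulative chord length of the 11 knots.  The
#' n output parameters comprise the 11 knot parameters plus interior values
#' allocated per segment in proportion to chord length, so the curve passes
#' through every original knot exactly.
#'
#' @param contour a [knot_contour()] or a k x 2 coordinate matrix
#'   (posterior to anterior).
#' @param n number of output points (default 100).
#' @return An object of class `dense_contour`: list with `points` (n x 2),
#'   `t` (parameter values), `knot_index` (positions of the original knots
#'   in `points`) and `source` (token key, if any).
#' @export
densify <- function(contour, n = 100L) {
  if (inherits(contour, "knot_contour")) {
    kn <- contour$knots
    src <- c(speaker = contour$speaker, token = contour$token)
  } else {
    kn <- as.matrix(contour)
    src <- NULL
  }
  k <- nrow(kn)
  if (k < 2L || !all(is.finite(kn))) stop("contour needs >= 2 finite knots")
  if (n < k) stop("n must be at least the number of knots")
  seg <- sqrt(rowSums((kn[-1, , drop = FALSE] - kn[-k, , drop = FALSE])^2))
  if (any(seg < 1e-12))
    stop("coincident consecutive knots (zero-length chord) at segment ",
         which(seg < 1e-12)[1])
  t_knot <- c(0, cumsum(seg))
  n_int <- n - k
  raw <- n_int * seg / sum(seg)
  base <- floor(raw)
  short <- n_int - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1L
  }
  tt <- t_knot
  for (i in seq_along(seg)) if (base[i] > 0)
    tt <- c(tt, t_knot[i] + seq_len(base[i]) / (base[i] + 1) * seg[i])
  tt <- sort(tt)
  fx <- stats::splinefun(t_knot, kn[, 1], method = "fmm")
  fy <- stats::splinefun(t_knot, kn[, 2], method = "fmm")
  pts <- cbind(x = fx(tt), y = fy(tt))
  structure(list(points = pts, t = tt,
                 knot_index = match(t_knot, tt), source = src),
            class = "dense_contour")
}

#' Wrap pre-computed points as a dense contour
#'
#' Used for analytic reference fixtures whose points are known in closed
#' form rather than obtained by spline interpolation.
#'
#' @param points an n x 2 coordinate matrix, ordered posterior to anterior.
#' @return A `dense_contour`.
#' @export
as_dense_contour <- function(points) {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), ncol(points) == 2L, nrow(points) >= 2L)
  colnames(points) <- c("x", "y")
  structure(list(points = points,
                 t = c(0, cumsum(sqrt(rowSums(diff(points)^2)))),
                 knot_index = NULL, source = NULL),
            class = "dense_contour")
}

#' Highest point on the tongue
#'
#' The contour point with the maximal y coordinate after occlusal rotation.
#' Ties are broken towards the smallest index (most posterior point).
#'
#' @param dense a `dense_contour`.
#' @param window optional integer pair of knot indices restricting the
#'   search to the stretch of contour between those knots (requires a
#'   spline-densified contour).  The default searches the whole contour.
#' @return Named numeric `c(x=, y=)` with attribute `index`.
#' @export
highest_point <- function(dense, window = NULL) {
  stopifnot(inherits(dense, "dense_contour"))
  idx <- seq_len(nrow(dense$points))
  if (!is.null(window)) {
    if (is.null(dense$knot_index))
      stop("knot window requires a spline-densified contour")
    lo <- dense$knot_index[window[1]]; hi <- dense$knot_index[window[2]]
    idx <- idx[idx >= lo & idx <= hi]
  }
  i <- idx[which.max(dense$points[idx, 2])]
  structure(c(x = unname(dense$points[i, 1]),
              y = unname(dense$points[i, 2])), index = i)
}

#' Highest vertex and its chord triangle
#'
#' The highest vertex (HV) is the contour point farthest, in perpendicular
#' distance, from the chord joining the vallecula (A, first point) to the
#' tongue tip (B, last point).  D is the orthogonal projection of HV onto
#' the chord line; the triangle side lengths AB, AD, DB and the apex height
#' HVD parameterise the curvature ratios.
#'
#' @param dense a `dense_contour`.
#' @return An object of class `triangle_geometry`: list with points `A`,
#'   `B`, `HV`, `D` and lengths `AB`, `AD`, `DB`, `HVD`.
#' @export
highest_vertex <- function(dense) {
  stopifnot(inherits(dense, "dense_contour"))
  p <- dense$points
  A <- p[1, ]; B <- p[nrow(p), ]
  ab <- B - A
  AB <- sqrt(sum(ab^2))
  if (AB < 1e-6)
    stop("degenerate contour: vallecula-tip chord shorter than 1e-6 mm")
  u <- ab / AB
  rel <- sweep(p, 2, A)
  perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
  i <- which.max(perp)
  HV <- p[i, ]
  AD <- sum((HV - A) * u)          # signed position of the foot along AB
  D <- A + AD * u
  structure(list(A = A, B = B, HV = HV, D = D,
                 AB = AB, AD = AD, DB = AB - AD, HVD = perp[i]),
            class = "triangle_geometry")
}

#' Triangle-based curvature ratios
#'
#' Tongue curvature position `TCP = HVD / AB` locates the apex relative to
#' the chord length; tongue curvature `TC = AD / DB` expresses where along
#' the chord the apex projects.  A flat contour (apex height below
#' `eps_flat`) has no meaningful apex: TCP is 0, TC is `NaN` and the
#' degeneracy flag is set.  An apex projecting onto the tongue tip
#' (`DB = 0`) yields `TC = Inf` with the flag set.
#'
#' @param tri a `triangle_geometry`.
#' @param eps_flat flatness threshold in mm (default 1e-6).
#' @return List with `tcp`, `tc`, `degenerate`.
#' @export
curvature_ratios <- function(tri, eps_flat = 1e-6) {
  stopifnot(inherits(tri, "triangle_geometry"), tri$AB > 0)
  if (tri$HVD < eps_flat)
    return(list(tcp = 0, tc = NaN, degenerate = TRUE))
  if (abs(tri$DB) < .Machine$double.eps * tri$AB)
    return(list(tcp = tri$HVD / tri$AB, tc = Inf, degenerate = TRUE))
  list(tcp = tri$HVD / tri$AB, tc = tri$AD / tri$DB, degenerate = FALSE)
}

#' Modified Curvature Index
#'
#' The integral of absolute curvature with respect to arc length,
#' \eqn{\int |\kappa(s)| ds}: the total absolute turning of the contour, in
#' radians.  The dense contour is resampled at `n_arc` points equally
#' spaced in cumulative arc length; derivatives are estimated by central
#' finite differences (one-sided at the ends), the curvature by
#' \eqn{\kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^{3/2}}, and the integral
#' by the trapezoid rule.  The result is invariant under rigid motion and
#' uniform scaling.
#'
#' @param dense a `dense_contour` with at least 5 points.
#' @param n_arc number of equal-arc-length sample points (default 100).
#' @return Non-negative scalar (radians of accumulated turning).
#' @export
mci <- function(dense, n_arc = 100L) {
  stopifnot(inherits(dense, "dense_contour"))
  p <- dense$points
  m <- n_arc
  if (nrow(p) < 5L || m < 5L) stop("MCI needs at least 5 points")
  seg <- sqrt(rowSums(diff(p)^2))
  if (any(seg <= 0)) stop("zero-length segment in dense contour")
  s <- c(0, cumsum(seg))
  se <- seq(0, s[length(s)], length.out = m)
  x <- stats::approx(s, p[, 1], xout = se)$y
  y <- stats::approx(s, p[, 2], xout = se)$y
  h <- se[2] - se[1]
  d1 <- function(v) c(v[2] - v[1],
                      (v[3:m] - v[1:(m - 2)]) / 2,
                      v[m] - v[m - 1]) / h
  d2 <- function(v) c(v[3] - 2 * v[2] + v[1],
                      v[3:m] - 2 * v[2:(m - 1)] + v[1:(m - 2)],
                      v[m] - 2 * v[m - 1] + v[m - 2]) / h^2
  xp <- d1(x); yp <- d1(y); xpp <- d2(x); ypp <- d2(y)
  kap <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  ak <- abs(kap)
  sum((ak[-1] + ak[-m]) / 2) * h
}

#' Extract the 16-measure battery for one token
#'
#' Knot-coordinate measures (K2_X..K7_X, K5_Y..K7_Y) are the raw landmark
#' coordinates; HP, HV, TCP, TC and MCI are computed from the spline-densified
#' contour.
#'
#' @param contour an occlusal-rotated [knot_contour()].
#' @param n_dense densification resolution (default 100 points).
#' @param hp_window optional knot-index pair restricting the highest-point
#'   search (e.g. `c(4, 8)` for a dorsum-only search); default searches the
#'   whole contour.
#' @return A one-row tibble: metadata, the 16 measures, and a `degenerate`
#'   flag for flat-contour TC.
#' @export
extract_measures <- function(contour, n_dense = 100L, hp_window = NULL) {
  stopifnot(inherits(contour, "knot_contour"))
  if (!contour$rotated)
    stop("token '", contour$token,
         "': measures require an occlusal-rotated contour")
  res <- tryCatch({
    dn <- densify(contour, n_dense)
    hp <- highest_point(dn, window = hp_window)
    tri <- highest_vertex(dn)
    cr <- curvature_ratios(tri)
    list(dn = dn, hp = hp, tri = tri, cr = cr, mci = mci(dn))
  }, error = function(e)
    stop("token '", contour$token, "': ", conditionMessage(e), call. = FALSE))
  kn <- unname(contour$knots)
  tibble::tibble(
    speaker = contour$speaker, token = contour$token,
    vowel = contour$vowel, repetition = contour$repetition,
    K2_X = kn[2, 1], K3_X = kn[3, 1], K4_X = kn[4, 1],
    K5_X = kn[5, 1], K6_X = kn[6, 1], K7_X = kn[7, 1],
    HP_X = unname(res$hp["x"]), HV_X = unname(res$tri$HV[1]),
    K5_Y = kn[5, 2], K6_Y = kn[6, 2], K7_Y = kn[7, 2],
    HP_Y = unname(res$hp["y"]), HV_Y = unname(res$tri$HV[2]),
    TCP = res$cr$tcp, TC = res$cr$tc, MCI = res$mci,
    degenerate = res$cr$degenerate)
}

#' Measure battery for a whole dataset
#'
#' @param dataset a [tongue_dataset()].
#' @inheritParams extract_measures
#' @return A tibble with one row per token (see [extract_measures()]).
#'   Degenerate (flat-contour) tokens are counted in a message.
#' @export
measure_table <- function(dataset, n_dense = 100L, hp_window = NULL) {
  stopifnot(inherits(dataset, "tongue_dataset"))
  out <- dplyr::bind_rows(lapply(dataset$contours, extract_measures,
                                 n_dense = n_dense, hp_window = hp_window))
  ndeg <- sum(out$degenerate)
  if (ndeg > 0)
    message(ndeg, " token(s) with degenerate (flat) contour: TC recorded as NaN")
  out
}
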