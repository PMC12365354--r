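#' Kruskal stress-1 of a configuration against dissimilarities
#'
#' Disparities are obtained by monotone (isotonic) regression of the
#' configuration distances on the input dissimilarities; stress-1 is
#' \eqn{\sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}} over all pairs,
#' where d are configuration distances and \eqn{\hat d} the disparities.
#'
#' @param diss a `dist` object or symmetric matrix of dissimilarities.
#' @param config an n x k configuration matrix.
#' @return Stress-1 in [0, 1].
#' @export
stress1 <- function(diss, config) {
  delta <- as.vector(stats::as.dist(diss))
  dconf <- as.vector(stats::dist(config))
  ord <- order(delta, dconf)
  dhat <- numeric(length(dconf))
  dhat[ord] <- stats::isoreg(dconf[ord])$yf
  denom <- sum(dconf^2)
  if (denom == 0) return(0)
  sqrt(sum((dconf - dhat)^2) / denom)
}

# rotate a centred configuration to its principal axes so column variances
# are non-increasing (axis 1 = largest variance); sign fixed so that the
# largest-magnitude loading on each axis is positive, for determinism
pca_rotate <- function(coords) {
  coords <- scale(coords, scale = FALSE)
  e <- eigen(stats::cov(coords), symmetric = TRUE)
  rot <- coords %*% e$vectors
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  rot
}

#' Per-speaker MDS reference vowel space
#'
#' Stacks each token's 11 landmark coordinates into a 22-dimensional vector
#' (x1..x11, y1..y11), computes Euclidean distances between tokens, and
#' ordains them in two dimensions.  The non-metric variant (default) runs
#' Kruskal-style MDS (`vegan::monoMDS`, global model) from the classical
#' (principal-coordinate) start plus `n_starts` random starts and keeps the
#' configuration with the lowest [stress1()]; the classical configuration
#' itself also competes.  The classical variant returns the
#' principal-coordinate solution, with stress-1 evaluated on it for
#' comparability.  The final configuration is PCA-rotated so MDS1 carries
#' the largest variance.
#'
#' @param contours list of [knot_contour()]s for one speaker, or an
#'   n x 22 numeric matrix of stacked coordinates.
#' @param variant `"nonmetric"` (default) or `"classical"`.
#' @param n_starts number of random restarts for the non-metric variant.
#' @param seed integer seed making the restarts reproducible.
#' @return An object of class `speaker_ordination`: list with `speaker`,
#'   `tokens`, `coords` (n x 2, columns MDS1, MDS2), `stress`, `variant`.
#' @export
speaker_mds <- function(contours, variant = c("nonmetric", "classical"),
                        n_starts = 20L, seed = 1L) {
  variant <- match.arg(variant)
  if (is.matrix(contours)) {
    X <- contours
    speaker <- NA_character_
    tokens <- rownames(X)
    if (is.null(tokens)) tokens <- as.character(seq_len(nrow(X)))
  } else {
    stopifnot(length(contours) >= 1, inherits(contours[[1]], "knot_contour"))
    X <- t(vapply(contours, function(k) c(k$knots[, 1], k$knots[, 2]),
                  numeric(22)))
    speaker <- contours[[1]]$speaker
    tokens <- vapply(contours, `[[`, "", "token")
  }
  n <- nrow(X)
  if (n < 5L) stop("speaker MDS needs at least 5 tokens")
  if (nrow(unique(round(X, 9))) < 3L)
    stop("fewer than 3 distinct token configurations")
  d <- stats::dist(X)
  cl <- stats::cmdscale(d, k = 2)
  if (variant == "classical") {
    coords <- pca_rotate(cl)
    st <- stress1(d, coords)
  } else {
    cand <- list(cl)
    st_cand <- stress1(d, cl)
    best <- cl; best_st <- st_cand
    with_seed(seed, {
      starts <- c(list(cl),
                  lapply(seq_len(n_starts),
                         function(i) matrix(stats::rnorm(2 * n), n, 2)))
      for (y0 in starts) {
        fit <- vegan::monoMDS(d, y = y0, k = 2, model = "global")
        s <- stress1(d, fit$points)
        if (s < best_st) { best <- fit$points; best_st <- s }
      }
    })
    # monoMDS configurations have arbitrary scale (stress-1 is
    # scale-invariant); rescale to the input dissimilarity scale so the
    # configuration distances are metrically comparable
    dc <- stats::dist(best)
    s2 <- sum(dc^2)
    if (s2 > 0) best <- best * sum(as.vector(d) * as.vector(dc)) / s2
    coords <- pca_rotate(best)
    st <- best_st
  }
  colnames(coords) <- c("MDS1", "MDS2")
  structure(list(speaker = speaker, tokens = tokens, coords = coords,
                 stress = st, variant = variant),
            class = "speaker_ordination")
}

#' @export
print.speaker_ordination <- function(x, ...) {
  cat("<speaker_ordination>", x$speaker, "-", nrow(x$coords), "tokens,",
      x$variant, "stress =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' Ordinate every speaker in a dataset
#'
#' @param dataset a [tongue_dataset()].
#' @inheritParams speaker_mds
#' @return Named list of [speaker_mds()] results, one per speaker.
#' @export
ordinate_speakers <- function(dataset, variant = "nonmetric",
                              n_starts = 20L, seed = 1L) {
  stopifnot(inherits(dataset, "tongue_dataset"))
  spk <- vapply(dataset$contours, `[[`, "", "speaker")
  by_spk <- split(dataset$contours, spk)
  out <- lapply(seq_along(by_spk), function(i)
    speaker_mds(by_spk[[i]], variant = variant, n_starts = n_starts,
                seed = seed + i))
  names(out) <- names(by_spk)
  out
}

#' Summarise per-speaker MDS stress
#'
#' @param ordinations list of `speaker_ordination` objects.
#' @return One-row tibble: `n_speakers`, `median`, `upper_quartile`.
#' @export
stress_summary <- function(ordinations) {
  st <- vapply(ordinations, `[[`, numeric(1), "stress")
  tibble::tibble(n_speakers = length(st),
                 median = stats::median(st),
                 upper_quartile = unname(stats::quantile(st, 0.75)))
}
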