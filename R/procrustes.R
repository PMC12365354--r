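#' Ordinary Procrustes superimposition
#'
#' Finds the similarity transform (rotation, uniform scale, translation; a
#' reflection is permitted by default) mapping `source` onto `target` with
#' least-squares residual, via the standard singular-value-decomposition
#' solution.  With `symmetric = TRUE` both configurations are first centred
#' and scaled to unit root sum of squares, which bounds the residual sum of
#' squares in [0, 1] and makes it symmetric in the two arguments -- the
#' appropriate normalisation when comparing a physical measure space against
#' an MDS space whose units are arbitrary.
#'
#' @param source,target n x k configurations with matching rows (same
#'   tokens, same order), n >= 3, no missing values.
#' @param allow_reflection permit an improper rotation (default TRUE: MDS
#'   axes have arbitrary orientation).
#' @param symmetric normalise both configurations first (default TRUE).
#' @return An object of class `procrustes_fit`: list with `rotation` (k x k
#'   orthogonal), `scale`, `translation`, `ss` (residual sum of squares),
#'   `fitted` (transformed source), plus the options used.
#' @export
procrustes_fit <- function(source, target, allow_reflection = TRUE,
                           symmetric = TRUE) {
  X <- as.matrix(target); Y <- as.matrix(source)
  if (any(dim(X) != dim(Y))) stop("source and target must match in shape")
  if (nrow(X) < 3L) stop("need at least 3 points")
  if (anyNA(X) || anyNA(Y)) stop("missing values must be dropped upstream")
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  ssY <- sum(Yc^2)
  if (ssY < 1e-24) stop("rank-deficient source: all points identical")
  if (symmetric) {
    Xc <- Xc / sqrt(sum(Xc^2))
    Yc <- Yc / sqrt(ssY)
    ssY <- 1
  }
  sv <- svd(crossprod(Xc, Yc))
  d <- sv$d
  V <- sv$v; U <- sv$u
  if (!allow_reflection) {
    s <- sign(det(V %*% t(U)))
    if (s < 0) {
      k <- ncol(V)
      V[, k] <- -V[, k]
      d[k] <- -d[k]
    }
  }
  R <- V %*% t(U)                     # maps source rows onto target rows
  scale <- sum(d) / ssY
  fitted <- scale * Yc %*% R
  ss <- sum((Xc - fitted)^2)
  translation <- xm - scale * drop(ym %*% R)
  structure(list(rotation = R, scale = scale, translation = translation,
                 ss = ss, fitted = sweep(fitted, 2, xm, `+`),
                 symmetric = symmetric, allow_reflection = allow_reflection),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> ss =", signif(x$ss, 6),
      if (x$symmetric) "(symmetric)" else "", "\n")
  invisible(x)
}

#' Rank all 64 measure pairs by Procrustes residual against the MDS spaces
#'
#' For each (position, height/shape) measure pair and each speaker, the
#' two-column physical configuration of that speaker's tokens is
#' superimposed on the speaker's MDS coordinates and the residual sum of
#' squares recorded; pairs are ranked by the across-speaker mean.  Measures
#' enter in raw mm -- the superimposition absorbs scale.  Tokens with a
#' non-finite measure value (flat-contour TC) are dropped pairwise for that
#' combination; a speaker left with fewer than 3 valid tokens is skipped
#' for that combination.
#'
#' @param measures a [measure_table()] tibble.
#' @param ordinations list of `speaker_ordination` objects named by speaker
#'   (see [ordinate_speakers()]).
#' @param allow_reflection,symmetric passed to [procrustes_fit()].
#' @param combos the measure pairs to sweep (default: all 64).
#' @return A tibble with columns `position`, `height_shape`, `mean_ss`,
#'   `n_speakers`, sorted ascending by `mean_ss`; per-speaker values in the
#'   attribute `per_speaker`.
#' @export
combo_sweep <- function(measures, ordinations, allow_reflection = TRUE,
                        symmetric = TRUE, combos = measure_combos()) {
  stopifnot(all(c("speaker", "token") %in% names(measures)))
  spk_measures <- split(measures, measures$speaker)
  miss <- setdiff(names(spk_measures), names(ordinations))
  if (length(miss)) stop("no ordination for speaker(s): ",
                         paste(miss, collapse = ", "))
  n_dropped <- 0L
  per_spk <- matrix(NA_real_, nrow(combos), length(spk_measures),
                    dimnames = list(NULL, names(spk_measures)))
  for (s in names(spk_measures)) {
    m <- spk_measures[[s]]
    ord <- ordinations[[s]]
    rows <- match(ord$tokens, m$token)
    if (anyNA(rows)) stop("speaker ", s, ": measures missing for token(s) ",
                          paste(ord$tokens[is.na(rows)], collapse = ", "))
    m <- m[rows, ]
    for (i in seq_len(nrow(combos))) {
      src <- cbind(m[[combos$position[i]]], m[[combos$height_shape[i]]])
      ok <- is.finite(src[, 1]) & is.finite(src[, 2])
      n_dropped <- n_dropped + sum(!ok)
      if (sum(ok) < 3L) next  # speaker skipped for this combo
      fit <- tryCatch(
        procrustes_fit(src[ok, , drop = FALSE],
                       ord$coords[ok, , drop = FALSE],
                       allow_reflection = allow_reflection,
                       symmetric = symmetric),
        error = function(e) NULL)
      if (!is.null(fit)) per_spk[i, s] <- fit$ss
    }
  }
  if (n_dropped > 0)
    message(n_dropped, " token-measure value(s) dropped pairwise (non-finite)")
  out <- combos
  out$mean_ss <- rowMeans(per_spk, na.rm = TRUE)
  out$n_speakers <- rowSums(!is.na(per_spk))
  out <- out[order(out$mean_ss), ]
  attr(out, "per_speaker") <- per_spk
  out
}
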