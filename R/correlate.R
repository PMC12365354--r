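#' By-speaker by-item means of scaled variables
#'
#' Reduces within-speaker-scaled values to one mean per (speaker, item)
#' cell per variable, where an item is one of the five word types; this
#' removes the repetition-level autocorrelation before correlation
#' analysis.  Non-finite values are dropped from the cell means.
#'
#' @param data a data frame with `speaker` and item columns, already
#'   within-speaker scaled (see [scale_within_speaker()]).
#' @param vars variables to average (default: the canonical measures plus
#'   any `f1_hz` / `f2_hz` columns present).
#' @param item name of the item column (default `"vowel"`).
#' @return A tibble with one row per (speaker, item) cell.
#' @export
speaker_item_means <- function(data, vars = NULL, item = "vowel") {
  stopifnot("speaker" %in% names(data), item %in% names(data))
  if (is.null(vars))
    vars <- intersect(c(measure_names()$all, "f1_hz", "f2_hz"), names(data))
  g <- data[, c("speaker", item, vars)]
  out <- stats::aggregate(
    g[vars], by = list(speaker = g$speaker, item = g[[item]]),
    FUN = function(x) if (any(is.finite(x))) mean(x[is.finite(x)]) else NaN)
  names(out)[2] <- item
  out <- out[order(out$speaker, out[[item]]), ]
  tibble::as_tibble(out)
}

#' Pairwise-complete Pearson correlation matrix
#'
#' @param data data frame of variables (typically [speaker_item_means()]
#'   output).
#' @param vars variables to correlate.
#' @return An object of class `correlation_matrix`: list with `r`
#'   (symmetric, unit diagonal) and `n` (pairwise complete sample sizes).
#'   A constant variable yields `NaN` correlations with a warning.
#' @export
correlation_table <- function(data, vars = NULL) {
  if (is.null(vars))
    vars <- intersect(c(measure_names()$all, "f1_hz", "f2_hz"), names(data))
  X <- as.matrix(data[, vars])
  X[!is.finite(X)] <- NA
  npair <- crossprod(!is.na(X))
  if (any(npair[upper.tri(npair)] < 3))
    stop("fewer than 3 complete pairs for some variable pair")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("constant variable(s): ",
            paste(vars[which(sds == 0)], collapse = ", "),
            "; correlations are NaN", call. = FALSE)
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  diag(r) <- 1
  structure(list(r = r, n = npair), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix>", nrow(x$r), "variables\n")
  print(round(x$r, 3))
  invisible(x)
}

#' Rank measures by correlation with each formant
#'
#' Joins by-speaker by-item measure means with equally reduced formant
#' means and returns, for each of F1 and F2, the 16 Pearson coefficients
#' sorted by absolute magnitude.
#'
#' @param measure_means [speaker_item_means()] of the scaled measures.
#' @param formant_means [speaker_item_means()] of the scaled formants
#'   (columns `f1_hz`, `f2_hz`).
#' @param item item column name.
#' @return List with tibbles `f1` and `f2` (columns `measure`, `r`, `n`),
#'   each 16 rows, sorted by |r| descending.
#' @export
formant_correlations <- function(measure_means, formant_means,
                                 item = "vowel") {
  merged <- dplyr::inner_join(measure_means, formant_means,
                              by = c("speaker", item))
  vars <- intersect(measure_names()$all, names(merged))
  cm <- correlation_table(merged, vars = c(vars, "f1_hz", "f2_hz"))
  one <- function(formant) {
    tb <- tibble::tibble(measure = vars,
                         r = cm$r[vars, formant],
                         n = cm$n[vars, formant])
    tb[order(abs(tb$r), decreasing = TRUE), ]
  }
  list(f1 = one("f1_hz"), f2 = one("f2_hz"))
}
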