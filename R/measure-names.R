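#' Canonical measure names
#'
#' The measure battery consists of eight tongue-position measures (x
#' coordinates) and eight tongue-height/shape measures (y coordinates and
#' shape indices).  Their cross product gives the 64 position-by-height/shape
#' pairs evaluated by the Procrustes and classification sweeps.
#'
#' @return `measure_names()` returns a list with components `position`,
#'   `height_shape` and `all`.
#' @export
measure_names <- function() {
  list(
    position     = c("K2_X", "K3_X", "K4_X", "K5_X", "K6_X", "K7_X",
                     "HP_X", "HV_X"),
    height_shape = c("K5_Y", "K6_Y", "K7_Y", "HP_Y", "HV_Y",
                     "TCP", "TC", "MCI"),
    all          = c("K2_X", "K3_X", "K4_X", "K5_X", "K6_X", "K7_X",
                     "HP_X", "HV_X",
                     "K5_Y", "K6_Y", "K7_Y", "HP_Y", "HV_Y",
                     "TCP", "TC", "MCI")
  )
}

#' All 64 position-by-height/shape measure pairs
#'
#' @param alias optional named character vector renaming measures in the
#'   output (e.g. `c(TCP = "TC", TC = "TCP")` to swap the two triangle-ratio
#'   labels); the underlying computation is unchanged.
#' @return A tibble with columns `position` and `height_shape`, 64 rows.
#' @export
measure_combos <- function(alias = NULL) {
  nm <- measure_names()
  out <- expand.grid(position = nm$position, height_shape = nm$height_shape,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!is.null(alias)) {
    out$position <- ifelse(out$position %in% names(alias),
                           alias[out$position], out$position)
    out$height_shape <- ifelse(out$height_shape %in% names(alias),
                               alias[out$height_shape], out$height_shape)
  }
  tibble::as_tibble(out)
}

# default vowel inventory: five lax monophthongs in a b_d frame
VOWELS_DEFAULT <- c("bid", "bed", "bad", "bod", "bud")

# run an expression under a fixed RNG state without disturbing the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
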