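#' Construct a single tongue-contour token
#'
#' A `knot_contour` holds the 11 ordered tongue-surface landmarks of one
#' vowel token, traversed posterior to anterior: knot 1 sits at the
#' vallecula, knots 2-3 on the tongue root, knots 5-7 on the dorsum and
#' knot 11 on the tongue tip.  Coordinates are in mm with x increasing
#' anteriorly and y superiorly (occlusal-plane orientation).
#'
#' @param speaker,token,vowel,repetition token metadata; `repetition` must be
#'   a positive integer.
#' @param knots an 11 x 2 numeric matrix of (x, y) coordinates in mm.
#' @param rotated logical; has the occlusal-plane rotation been applied?
#' @return An object of class `knot_contour`.
#' @export
knot_contour <- function(speaker, token, vowel, repetition, knots,
                         rotated = TRUE) {
  knots <- as.matrix(knots)
  if (!is.numeric(knots) || nrow(knots) != 11L || ncol(knots) != 2L)
    stop("token '", token, "': knots must be an 11 x 2 numeric matrix")
  if (!all(is.finite(knots)))
    stop("token '", token, "': non-finite knot coordinate")
  if (length(repetition) != 1L || is.na(repetition) || repetition < 1 ||
      repetition != round(repetition))
    stop("token '", token, "': repetition must be a positive integer")
  dimnames(knots) <- list(NULL, c("x", "y"))
  structure(
    list(speaker = as.character(speaker), token = as.character(token),
         vowel = as.character(vowel), repetition = as.integer(repetition),
         knots = knots, rotated = isTRUE(rotated)),
    class = "knot_contour")
}

#' @export
print.knot_contour <- function(x, ...) {
  cat("<knot_contour> speaker", x$speaker, "token", x$token,
      "vowel", x$vowel, "rep", x$repetition,
      if (x$rotated) "(occlusal-rotated)" else "(unrotated)", "\n")
  invisible(x)
}

#' Bundle contours and optional formant records into a dataset
#'
#' @param contours a list of [knot_contour()] objects.
#' @param formants optional data frame with columns `speaker`, `token`,
#'   `f1_hz`, `f2_hz` (vowel-midpoint formants); every row must match a
#'   contour by (speaker, token).
#' @return An object of class `tongue_dataset`.
#' @export
tongue_dataset <- function(contours, formants = NULL) {
  stopifnot(is.list(contours), length(contours) > 0L)
  keys <- vapply(contours, function(k) paste(k$speaker, k$token, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (speaker, token) keys: ",
         paste(unique(gsub("\r", "/", keys[duplicated(keys)])),
               collapse = ", "))
  if (!is.null(formants)) {
    formants <- tibble::as_tibble(formants)
    need <- c("speaker", "token", "f1_hz", "f2_hz")
    if (!all(need %in% names(formants)))
      stop("formant table must have columns ",
           paste(need, collapse = ", "))
    bad <- !is.finite(formants$f1_hz) | !is.finite(formants$f2_hz) |
      formants$f1_hz <= 0 | formants$f2_hz <= formants$f1_hz
    if (any(bad))
      stop("invalid formant record (need 0 < F1 < F2) for token(s): ",
           paste(formants$token[bad], collapse = ", "))
    fk <- paste(formants$speaker, formants$token, sep = "\r")
    if (anyDuplicated(fk)) stop("duplicate formant records")
    orphan <- !(fk %in% keys)
    if (any(orphan))
      stop("formant record without matching contour: ",
           paste(formants$token[orphan], collapse = ", "))
  }
  structure(list(contours = contours, formants = formants),
            class = "tongue_dataset")
}

#' @export
print.tongue_dataset <- function(x, ...) {
  cat("<tongue_dataset>", length(x$contours), "contours,",
      if (is.null(x$formants)) "no formants"
      else paste(nrow(x$formants), "formant records"), "\n")
  invisible(x)
}

#' Tabulate the landmarks of a dataset in long form
#'
#' @param dataset a [tongue_dataset()].
#' @return A tibble with columns speaker, token, vowel, repetition, knot,
#'   x, y (one row per landmark).
#' @export
contours_long <- function(dataset) {
  stopifnot(inherits(dataset, "tongue_dataset"))
  rows <- lapply(dataset$contours, function(k)
    tibble::tibble(speaker = k$speaker, token = k$token, vowel = k$vowel,
                   repetition = k$repetition, knot = 1:11,
                   x = k$knots[, 1], y = k$knots[, 2]))
  dplyr::bind_rows(rows)
}

#' Read a tongue-landmark table
#'
#' Two dialects are supported.  `long` is the package's canonical export: one
#' row per landmark with columns `speaker, token, vowel, repetition, knot, x,
#' y`.  `wide` matches one-row-per-token exports with columns
#' `speaker, token, vowel, repetition, x1..x11, y1..y11`.  Accessory
#' landmarks (hyoid, mandible, short tendon), if present as knot indices
#' above 11, are dropped: no measure uses them.
#'
#' @param path CSV file (UTF-8, "." decimal, header mandatory).
#' @param dialect `"long"` or `"wide"`.
#' @param vowels permitted vowel labels.
#' @param label_map optional named character vector mapping raw labels in the
#'   file to canonical ones; unknown labels not covered by the map are a hard
#'   error.
#' @param rotated are the coordinates already occlusal-plane rotated?
#'   Exports from the acquisition pipeline normally are.
#' @return A [tongue_dataset()] (without formants).
#' @export
read_contours <- function(path, dialect = c("long", "wide"),
                          vowels = VOWELS_DEFAULT, label_map = NULL,
                          rotated = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  meta_cols <- c("speaker", "token", "vowel", "repetition")
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !(v %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric ", what, " at data row ", bad[1], ": '", v[bad[1]], "'")
    out
  }
  if (dialect == "long") {
    need <- c(meta_cols, "knot", "x", "y")
    if (!all(need %in% names(raw)))
      stop("long dialect needs columns ", paste(need, collapse = ", "),
           "; missing: ", paste(setdiff(need, names(raw)), collapse = ", "))
    raw$knot <- num(raw$knot, "knot index")
    raw$x <- num(raw$x, "x coordinate")
    raw$y <- num(raw$y, "y coordinate")
    raw <- raw[raw$knot <= 11, , drop = FALSE]  # accessory landmarks ignored
    sp <- split(raw, paste(raw$speaker, raw$token, sep = "\r"))
    contours <- lapply(sp, function(d) {
      tok <- d$token[1]
      if (anyDuplicated(d$knot))
        stop("token '", tok, "': duplicate knot index ",
             d$knot[duplicated(d$knot)][1])
      if (!setequal(d$knot, 1:11))
        stop("token '", tok, "': expected knot indices 1..11, got ",
             nrow(d), " knots")
      d <- d[order(d$knot), ]
      knot_contour(d$speaker[1], tok,
                   resolve_vowel(d$vowel[1], vowels, label_map, tok),
                   num(d$repetition, "repetition")[1],
                   cbind(d$x, d$y), rotated = rotated)
    })
  } else {
    xcols <- paste0("x", 1:11); ycols <- paste0("y", 1:11)
    need <- c(meta_cols, xcols, ycols)
    if (!all(need %in% names(raw)))
      stop("wide dialect needs columns ", paste(need, collapse = ", "),
           "; missing: ", paste(setdiff(need, names(raw)), collapse = ", "))
    contours <- lapply(seq_len(nrow(raw)), function(i) {
      xs <- num(unlist(raw[i, xcols]), "x coordinate")
      ys <- num(unlist(raw[i, ycols]), "y coordinate")
      knot_contour(raw$speaker[i], raw$token[i],
                   resolve_vowel(raw$vowel[i], vowels, label_map,
                                 raw$token[i]),
                   num(raw$repetition, "repetition")[i],
                   cbind(xs, ys), rotated = rotated)
    })
  }
  names(contours) <- NULL
  check_anterior_ordering(contours)
  tongue_dataset(contours)
}

resolve_vowel <- function(v, vowels, label_map, token) {
  if (!is.null(label_map) && v %in% names(label_map)) v <- label_map[[v]]
  if (!(v %in% vowels))
    stop("token '", token, "': unknown vowel label '", v,
         "' (supply label_map or extend vowels)")
  v
}

# well-formed occlusal-rotated contours run posterior -> anterior with
# strictly increasing x; violations are flagged, not fatal
check_anterior_ordering <- function(contours) {
  bad <- vapply(contours,
                function(k) k$rotated && any(diff(k$knots[, 1]) <= 0),
                logical(1))
  if (any(bad))
    warning("x not strictly increasing posterior->anterior for token(s): ",
            paste(vapply(contours[bad], `[[`, "", "token"), collapse = ", "),
            call. = FALSE)
  invisible(NULL)
}

#' Read a vowel-midpoint formant table
#'
#' @param path CSV with columns `speaker, token, f1_hz, f2_hz`.
#' @return A tibble, validated (0 < F1 < F2).
#' @export
read_formants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  f <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("speaker", "token", "f1_hz", "f2_hz")
  if (!all(need %in% names(f)))
    stop("formant table needs columns ", paste(need, collapse = ", "))
  bad <- !is.finite(f$f1_hz) | !is.finite(f$f2_hz) |
    f$f1_hz <= 0 | f$f2_hz <= f$f1_hz
  if (any(bad))
    stop("invalid formant record (need 0 < F1 < F2) for token(s): ",
         paste(f$token[bad], collapse = ", "))
  f
}

#' Apply the occlusal-plane rotation to a contour
#'
#' Rotates all landmarks rigidly by `-occlusal_angle` about the coordinate
#' origin so that the bite plane becomes horizontal.  Inter-knot distances
#' are preserved exactly (rigid motion).
#'
#' @param contour an unrotated [knot_contour()].
#' @param occlusal_angle bite-plane angle in radians, |angle| <= pi/2; the
#'   angle is taken as supplied (the acquisition software's sign convention
#'   is not standardised), with positive values measured counter-clockwise
#'   from the x axis.
#' @return The rotated contour, with its `rotated` flag set.
#' @export
rotate_to_occlusal <- function(contour, occlusal_angle) {
  stopifnot(inherits(contour, "knot_contour"))
  if (contour$rotated)
    stop("token '", contour$token, "': already occlusal-rotated")
  if (!is.finite(occlusal_angle) || abs(occlusal_angle) > pi / 2)
    stop("implausible occlusal angle (|angle| > pi/2): ", occlusal_angle)
  a <- -occlusal_angle
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  contour$knots <- contour$knots %*% t(R)
  colnames(contour$knots) <- c("x", "y")
  contour$rotated <- TRUE
  contour
}

#' Write / read a per-token measure table
#'
#' The CSV has one row per token: metadata columns (speaker, token, vowel,
#' repetition) followed by the 16 measure columns in canonical order and a
#' `degenerate` flag.  `NaN` measures (flat-contour TC) are serialised as
#' empty fields and restored as `NaN` on reading, so write-then-read is the
#' identity.
#'
#' @param records a measure table as produced by [measure_table()].
#' @param path output CSV path.
#' @return `write_measures()` returns `path` invisibly; `read_measures()`
#'   returns the tibble.
#' @export
write_measures <- function(records, path) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) stop("no measure records to write")
  need <- c("speaker", "token", "vowel", "repetition", measure_names()$all)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("measure table missing columns: ",
                         paste(miss, collapse = ", "))
  ok <- tryCatch({
    utils::write.csv(records[, c(need, intersect("degenerate",
                                                 names(records)))],
                     path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write measures to ", path)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                         na.strings = c("", "NA")))
  for (v in intersect(measure_names()$all, names(m)))
    m[[v]][is.na(m[[v]])] <- NaN
  m
}
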