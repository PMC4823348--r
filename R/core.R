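# Core arithmetic shared by the writer, reader and validator: the uniform
# time axis, path-style unique identifiers, the unit grammar and the
# NaN-padding used by the NANPADDED storage variant.

#' Sampling times of a uniformly sampled dataset
#'
#' Computes the time axis of a block sampled at a constant interval: the
#' column with 0-based index j samples time `tstart + j * dt` (equivalently,
#' the n-th sample in 1-based counting falls at `tstart + (n - 1) * dt`).
#'
#' @param tstart start time
#' @param dt sampling interval, must be positive
#' @param n number of samples (>= 0)
#' @return numeric vector of `n` sampling times
#' @examples
#' uniformTimeAxis(0, 1e-4, 5)
#' @export
uniformTimeAxis <- function(tstart, dt, n) {
  stopifnot(is.numeric(tstart), is.numeric(dt), length(dt) == 1L)
  if (is.na(dt) || dt <= 0) stop("'dt' must be positive")
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("'n' must be a nonnegative count")
  tstart + (seq_len(n) - 1) * dt
}

#' Path-style unique identifiers
#'
#' For models stored as a tree, the absolute path of a component doubles as
#' its unique identifier.  `makeUid()` joins path components with `/` into
#' an absolute path; `uidComponents()` is its inverse.
#'
#' @param components character vector of path components; none may be empty
#'   or contain `/`
#' @return `makeUid()`: a single uid string starting with `/`;
#'   `uidComponents()`: the character vector of components
#' @examples
#' makeUid(c("model", "modeltree", "neuronA", "soma"))
#' uidComponents("/model/modeltree/neuronA/soma")
#' @export
makeUid <- function(components) {
  components <- as.character(components)
  if (!length(components) || any(!nzchar(components)))
    stop("'components' must be a nonempty list of nonempty strings")
  if (any(grepl("/", components, fixed = TRUE)))
    stop("components must not contain the separator '/'")
  paste0("/", paste(components, collapse = "/"))
}

#' @rdname makeUid
#' @param uid a uid string produced by `makeUid()`
#' @export
uidComponents <- function(uid) {
  stopifnot(is.character(uid), length(uid) == 1L)
  comps <- strsplit(sub("^/", "", uid), "/", fixed = TRUE)[[1L]]
  if (!length(comps) || any(!nzchar(comps))) stop("malformed uid")
  comps
}

## unit grammar -------------------------------------------------------------

# Closed UDUNITS-style subset: SI prefixes x a fixed base-unit list, with
# '/', '*' and integer powers.  "ohm" is written in full (the SI symbol is
# non-ASCII).  "cm2" and "cm^2" are both accepted; normalisation inserts
# the '^'.
.unit_prefixes <- c("da", "Y", "Z", "E", "P", "T", "G", "M", "k", "h",
                    "d", "c", "m", "u", "n", "p", "f", "a", "z", "y")
.unit_bases <- c("ohm", "mol", "Hz", "cd", "kg", "m", "s", "A", "V", "S",
                 "F", "M", "C", "K", "g", "L")

.unit_token_ok <- function(sym) {
  if (sym %in% .unit_bases) return(TRUE)
  for (p in .unit_prefixes) {
    if (startsWith(sym, p) && nchar(sym) > nchar(p) &&
        substring(sym, nchar(p) + 1L) %in% .unit_bases)
      return(TRUE)
  }
  FALSE
}

#' Validate and normalise a unit string
#'
#' Checks a unit string against the unit grammar used for the mandatory
#' `unit` attribute: SI base units with standard prefixes, combined with
#' `/`, `*` and integer powers (`mS/cm^2`, `mV`, `s^-1`).  The empty string
#' is legal only where a field carries no physical unit (e.g. an index
#' column) and `allowEmpty` is set.  `validateUnit()` returns the
#' normalised string (powers written with `^`) or throws an error;
#' `isValidUnit()` is the vectorised predicate.
#'
#' @param unit unit string
#' @param allowEmpty accept the empty string?
#' @return `validateUnit()`: the normalised unit string
#' @examples
#' validateUnit("mS/cm2")   # -> "mS/cm^2"
#' isValidUnit(c("mV", "furlong"))
#' @export
validateUnit <- function(unit, allowEmpty = FALSE) {
  stopifnot(is.character(unit), length(unit) == 1L)
  if (is.na(unit)) stop("unit must not be NA")
  if (grepl("[^\x20-\x7e]", unit, useBytes = TRUE))
    stop("unit contains non-ASCII characters; write symbols like 'ohm' in full")
  u <- gsub("[ \t]+", "*", trimws(unit))
  if (!nzchar(u)) {
    if (allowEmpty) return("")
    stop("empty unit string is only allowed for non-physical fields")
  }
  tok_re <- "[A-Za-z]+(\\^-?[0-9]+|-?[0-9]+)?|[*/]"
  toks <- regmatches(u, gregexpr(tok_re, u))[[1L]]
  if (paste(toks, collapse = "") != u)
    stop(sprintf("cannot parse unit '%s'", unit))
  out <- character(length(toks))
  expect_unit <- TRUE
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (t %in% c("*", "/")) {
      if (expect_unit) stop(sprintf("misplaced operator in unit '%s'", unit))
      out[i] <- t
      expect_unit <- TRUE
    } else {
      if (!expect_unit) stop(sprintf("missing operator in unit '%s'", unit))
      m <- regmatches(t, regexec("^([A-Za-z]+)(\\^?(-?[0-9]+))?$", t))[[1L]]
      sym <- m[2L]
      pow <- m[4L]
      if (!.unit_token_ok(sym))
        stop(sprintf("unknown unit symbol '%s' in '%s'", sym, unit))
      out[i] <- if (nzchar(pow)) paste0(sym, "^", pow) else sym
      expect_unit <- FALSE
    }
  }
  if (expect_unit) stop(sprintf("unit '%s' ends with an operator", unit))
  paste(out, collapse = "")
}

#' @rdname validateUnit
#' @export
isValidUnit <- function(unit, allowEmpty = FALSE) {
  vapply(unit, function(u) {
    !inherits(tryCatch(validateUnit(u, allowEmpty), error = identity),
              "error")
  }, logical(1L), USE.NAMES = FALSE)
}

## NaN padding --------------------------------------------------------------

#' Pad ragged rows into a regular matrix with trailing NaN
#'
#' Stacks unequal-length rows into a 2D matrix whose width is the maximum
#' row length, filling the tail of shorter rows with NaN.  NaN is reserved
#' as the padding sentinel, so rows containing NaN (or NA) payload are
#' rejected.  `nanUnpad()` inverts the operation, truncating each row at
#' its first NaN; a NaN followed by a valid value (an interior NaN) is a
#' format error.
#'
#' @param rows list of numeric vectors
#' @return `nanPad()`: a `length(rows)` x `max(lengths(rows))` matrix;
#'   `nanUnpad()`: a list of numeric vectors
#' @examples
#' m <- nanPad(list(c(1, 2), 3))
#' nanUnpad(m)
#' @export
nanPad <- function(rows) {
  if (!is.list(rows) || !length(rows)) stop("'rows' must be a nonempty list")
  rows <- lapply(rows, as.numeric)
  if (any(vapply(rows, anyNA, logical(1L))))
    stop("rows must not contain NaN/NA: NaN is reserved as the padding sentinel")
  w <- max(lengths(rows))
  out <- matrix(NaN, nrow = length(rows), ncol = w)
  for (i in seq_along(rows)) {
    k <- length(rows[[i]])
    if (k) out[i, seq_len(k)] <- rows[[i]]
  }
  out
}

#' @rdname nanPad
#' @param mat a 2D numeric matrix in which NaNs, if any, form a contiguous
#'   suffix of each row
#' @export
nanUnpad <- function(mat) {
  stopifnot(is.matrix(mat))
  lapply(seq_len(nrow(mat)), function(i) {
    row <- mat[i, ]
    bad <- which(is.na(row))
    if (!length(bad)) return(as.numeric(row))
    first <- bad[1L]
    if (any(!is.na(row[first:length(row)])))
      stop(sprintf("interior NaN in row %d: valid value after padding", i))
    as.numeric(row[seq_len(first - 1L)])
  })
}

# internal: per-row payload lengths of a NaN-padded matrix
.nan_row_lengths <- function(mat) lengths(nanUnpad(mat))
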