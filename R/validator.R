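# Conformance validator: a fixed rule set with stable ids, machine-readable
# findings and the model-description precedence resolution.
#
# R1  level-1 groups /data and /map present (/model recommended)
# R2  level-2 category names within the defined set
# R3  unit attribute present (and inside the unit grammar) on physical
#     datasets
# R4  a resolvable source mapping for every dataset under /data
# R5  uniform timing present: tstart/dt attributes or a time scale
# R6  NaN-padded datasets obey the trailing-padding rule
# R7  ONED map tables bidirectionally consistent with `source` attributes
# R8  one storage variant per category per file
# R9  root metadata attributes present
# R10 timestamps parse as ISO 8601
# R11 modeltree uids unique
# R12 ragged nonuniform time stores congruent with the values
.validator_rules <- paste0("R", 1:12)

.finding <- function(severity, rule, node, message) {
  data.frame(severity = severity, rule = rule, node = node,
             message = message, stringsAsFactors = FALSE)
}

.mandatory_root_attrs <- c("title", "creator", "created", "software",
                           "method", "nsdf_version")

#' Validate an NSDF file
#'
#' Runs the full conformance rule set (R1-R12, see the package vignette)
#' against a file and returns a machine-readable report.  The default
#' tolerant mode mirrors the format's "recommended" language: unit strings
#' outside the supported grammar and missing optional metadata are
#' warnings.  Strict mode promotes both to errors.  Validation is
#' read-only and idempotent.
#'
#' @param path file to validate
#' @param strict promote recommendation-level findings to errors?
#' @return an \linkS4class{NSDFValidation}; `conforms(report)` is `TRUE`
#'   when no error-severity findings were raised, `findings(report)`
#'   returns the finding table
#' @examples
#' f <- tempfile(fileext = ".h5")
#' writeBundle(genTwoNeurons(seed = 0), f)
#' conforms(validateNSDF(f))
#' @export
validateNSDF <- function(path, strict = FALSE) {
  fl <- list()
  add <- function(severity, rule, node, message)
    fl[[length(fl) + 1L]] <<- .finding(severity, rule, node, message)
  done <- function() {
    f <- if (length(fl)) do.call(rbind, fl) else
      .finding(character(), character(), character(), character())[0L, ]
    new("NSDFValidation", path = path, findings = f, strict = strict)
  }
  if (!file.exists(path) || !isTRUE(tryCatch(rhdf5::H5Fis_hdf5(path),
                                             error = function(e) FALSE))) {
    add("error", "R1", "/", "file is unreadable or not an HDF5 file")
    return(done())
  }
  gradeOpt <- if (strict) "error" else "warning"

  ## R1: level-1 groups.  When /map itself is missing the per-dataset
  ## mapping rules (R4/R7/R12) are implied by R1 and skipped.
  mapMissing <- !identical(.h5kind(path, "/map"), "group")
  for (g in c("/data", "/map"))
    if (!identical(.h5kind(path, g), "group"))
      add("error", "R1", g, "mandatory level-1 group is missing")
  if (!identical(.h5kind(path, "/model"), "group"))
    add("info", "R1", "/model",
        "no /model group; a model description is recommended")
  if (!.h5exists(path, "/data")) return(done())

  ## R2: level-2 category names
  for (cat in setdiff(.h5children(path, "/data"), .categories))
    add("error", "R2", paste0("/data/", cat),
        "unknown data category (must be static/uniform/nonuniform/event)")
  for (cat in setdiff(.h5children(path, "/map"),
                      c(.categories, "time")))
    add("error", "R2", paste0("/map/", cat),
        "unknown map category")

  ## walk the data tree once
  entries <- list()
  for (cat in intersect(.h5children(path, "/data"), .categories)) {
    for (pop in .h5children(path, paste0("/data/", cat))) {
      for (var in .h5children(path, sprintf("/data/%s/%s", cat, pop))) {
        v <- .detect_variant(path, cat, pop, var)
        entries[[length(entries) + 1L]] <-
          list(cat = cat, pop = pop, var = var, variant = v,
               path = .data_path(cat, pop, var))
        if (is.na(v))
          add("error", "R2", .data_path(cat, pop, var),
              "layout matches no storage variant")
      }
    }
  }

  check_unit_attr <- function(node, nfields = NULL) {
    a <- .h5attrs(path, node)
    u <- a$unit
    if (is.null(u)) {
      add("error", "R3", node,
          "dataset representing a physical quantity lacks a unit attribute")
      return(invisible(NULL))
    }
    u <- as.character(u)
    if (!is.null(nfields) && length(u) > 1L && length(u) != nfields)
      add("error", "R3", node,
          sprintf("unit array has %d entries for %d fields",
                  length(u), nfields))
    if (all(!nzchar(u)) && is.null(nfields))
      add("error", "R3", node, "unit attribute is empty")
    bad <- u[nzchar(u) & !isValidUnit(u, allowEmpty = TRUE)]
    if (length(bad))
      add(gradeOpt, "R3", node,
          paste("unit string(s) outside the supported grammar:",
                paste(sQuote(bad), collapse = ", ")))
  }

  check_source_scale <- function(node, expectRows = NULL) {
    if (mapMissing) return(invisible(NULL))
    sc <- tryCatch(.scales_by_class(path, node, 0L),
                   error = function(e) NULL)
    if (is.null(sc) || !length(sc$string)) {
      add("error", "R4", node,
          "no resolvable source mapping (no source dimension scale attached)")
      return(invisible(NULL))
    }
    if (!is.null(expectRows)) {
      n <- .dset_dims(path, sc$string[[1L]])[1L]
      if (n != expectRows)
        add("error", "R4", node, sprintf(
          "source scale has %d uid(s) for %d row(s)", n, expectRows))
    }
  }

  for (e in entries) {
    if (is.na(e$variant)) next
    node <- e$path
    if (e$variant == "ONED") {
      if (mapMissing) next
      ## R7 + R4 + R3 on the per-source datasets and the map table
      tbl <- tryCatch(.oned_table(path, e$cat, e$pop, e$var),
                      error = function(err) NULL)
      kids <- .h5children(path, node)
      kid_paths <- file.path(node, kids)
      if (is.null(tbl)) {
        add("error", "R4", node,
            "ONED variable has no source/data map table")
      } else {
        map <- .read_map_table(path, tbl)
        for (i in seq_len(nrow(map))) {
          if (!.h5exists(path, map$data[i])) {
            add("error", "R7", tbl, sprintf(
              "map row %d points to missing dataset %s", i, map$data[i]))
            next
          }
          srcattr <- as.character(
            .attr1(.h5attrs(path, map$data[i]), "source", ""))
          if (!identical(srcattr, map$source[i]))
            add("error", "R7", map$data[i], sprintf(
              "source attribute '%s' does not match map entry '%s'",
              srcattr, map$source[i]))
        }
        orphan <- setdiff(kid_paths, map$data)
        for (o in orphan)
          add("error", "R7", o, "dataset missing from the map table")
      }
      for (k in kid_paths) {
        check_unit_attr(k)
        if (!nzchar(as.character(.attr1(.h5attrs(path, k), "source", ""))))
          add("error", "R4", k, "ONED dataset lacks a source attribute")
        if (e$cat == "nonuniform" &&
            !length(.scales_by_class(path, k, 0L)$float1d))
          add("error", "R12", k, "no sampling-time scale attached")
      }
      next
    }
    check_unit_attr(node,
                    nfields = if (e$cat == "static" &&
                                  .dtype_class(path, node) == "compound") {
                      length(rhdf5::h5read(path, node,
                                           compoundAsDataFrame = TRUE))
                    })
    P <- .dset_dims(path, node)[1L]
    check_source_scale(node, expectRows = P)
    if (e$cat == "uniform") {
      a <- .h5attrs(path, node)
      hasAttrs <- !is.null(a$tstart) && !is.null(a$dt)
      hasScale <- length(.scales_by_class(path, node, 1L)$float1d) > 0L
      if (!hasAttrs && !hasScale)
        add("error", "R5", node,
            "uniform dataset has neither tstart/dt attributes nor a time scale")
    }
    if (e$variant == "NANPADDED") {
      mat <- .read_matrix(path, node)
      bad <- which(vapply(seq_len(nrow(mat)), function(i) {
        row <- mat[i, ]
        nas <- which(is.na(row))
        length(nas) > 0L && any(!is.na(row[nas[1L]:length(row)]))
      }, logical(1L)))
      for (i in bad)
        add("error", "R6", node,
            sprintf("row %d has an interior NaN (padding must be a suffix)",
                    i))
      if (e$cat == "nonuniform" && !mapMissing) {
        sc1 <- .scales_by_class(path, node, 1L)
        if (!length(sc1$float2d)) {
          add("error", "R12", node,
              "no NaN-padded sampling-time matrix attached")
        } else if (!length(bad)) {
          tmat <- .read_matrix(path, sc1$float2d[[1L]])
          if (!identical(dim(tmat), dim(mat)) ||
              !identical(is.na(tmat), is.na(mat)))
            add("error", "R12", node,
                "NaN masks of values and sampling times differ")
        }
      }
    }
    if (e$variant == "VLEN" && e$cat == "nonuniform" && !mapMissing) {
      sc0 <- .scales_by_class(path, node, 0L)
      if (!length(sc0$vlen)) {
        add("error", "R12", node,
            "no ragged sampling-time scale attached")
      } else {
        vl <- lengths(.vlen_read(path, node))
        tl <- lengths(.vlen_read(path, sc0$vlen[[1L]]))
        if (!identical(vl, tl))
          add("error", "R12", node,
              "per-source value and sampling-time lengths differ")
      }
    }
  }

  ## R8: variant consistency per category
  for (cat in c("nonuniform", "event")) {
    vs <- unique(stats::na.omit(vapply(
      Filter(function(e) e$cat == cat, entries),
      function(e) e$variant, character(1L))))
    if (length(vs) > 1L)
      add("error", "R8", paste0("/data/", cat), paste(
        "mixed storage variants within one category:",
        paste(vs, collapse = ", ")))
  }

  ## R9/R10: root metadata
  ra <- .h5attrs(path, "/")
  for (nm in .mandatory_root_attrs)
    if (is.null(ra[[nm]]))
      add("error", "R9", "/",
          paste0("missing mandatory root attribute '", nm, "'"))
  for (nm in c("created", "tstart", "tend")) {
    v <- ra[[nm]]
    if (!is.null(v) && any(nzchar(v)) &&
        !all(.is_iso8601(as.character(v)[nzchar(as.character(v))])))
      add("error", "R10", "/", paste0(
        "root attribute '", nm, "' is not an ISO 8601 date-time"))
  }

  ## R11: modeltree uid uniqueness
  if (.h5exists(path, "/model/modeltree")) {
    uids <- .modeltree_uids(path)
    dup <- unique(uids[duplicated(uids)])
    for (u in dup)
      add("error", "R11", "/model/modeltree",
          paste0("duplicate uid '", u, "' in the model tree"))
  }

  done()
}

#' Resolve the model-description precedence order
#'
#' A file may carry several model descriptions; readers interpret them in
#' the fixed precedence order model tree, then file contents, then file
#' references, then external links.  Returns the kinds present and the
#' selected (highest-precedence) one; a file with no model description is
#' legal and selects `"none"`.
#'
#' @param path an NSDF file
#' @return list with elements `present` (character vector in precedence
#'   order) and `selected` (a single kind or `"none"`)
#' @export
resolveModelPrecedence <- function(path) {
  order <- c("modeltree", "filecontents", "filerefs", "links")
  present <- character()
  for (k in order) {
    g <- paste0("/model/", k)
    if (.h5exists(path, g) && length(.h5children(path, g)))
      present <- c(present, k)
  }
  list(present = present,
       selected = if (length(present)) present[1L] else "none")
}

#' Serialise a validation report to JSON
#'
#' @param x an \linkS4class{NSDFValidation}
#' @return a JSON string with the per-finding table, summary counts and
#'   the conformance verdict
#' @export
validationToJSON <- function(x) {
  stopifnot(is(x, "NSDFValidation"))
  f <- x@findings
  jsonlite::toJSON(list(
    path = x@path, strict = x@strict, conforms = conforms(x),
    counts = list(error = sum(f$severity == "error"),
                  warning = sum(f$severity == "warning"),
                  info = sum(f$severity == "info")),
    findings = f), auto_unbox = TRUE, pretty = TRUE)
}
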