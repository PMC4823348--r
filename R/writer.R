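# Writer: lays out /data, /map and /model, attaches source and time
# dimension scales, and supports all storage variants plus streaming append.

.data_path <- function(cat, pop, var) sprintf("/data/%s/%s/%s", cat, pop, var)
.scale_path <- function(cat, pop) sprintf("/map/%s/%s", cat, pop)
.table_path <- function(cat, pop, var) sprintf("/map/%s/%s/%s", cat, pop, var)
.time_path <- function(cat, pop, var, i = NULL) {
  nm <- paste(cat, pop, var, sep = "_")
  if (!is.null(i)) nm <- sprintf("%s_%d", nm, i)
  paste0("/map/time/", nm)
}

# deterministic level-5 dataset names for the ONED variant: the uid leaf,
# made filesystem-safe, with an index suffix on collision
.oned_names <- function(uids) {
  leaf <- gsub("[^A-Za-z0-9_.-]", "_", sub(".*/", "", uids))
  if (any(!nzchar(leaf)) || anyDuplicated(leaf))
    leaf <- paste0(ifelse(nzchar(leaf), leaf, "src"), "_",
                   seq_along(leaf) - 1L)
  leaf
}

.check_handle <- function(h) {
  stopifnot(is(h, "NSDFFile"))
  if (!file.exists(h@path)) stop("NSDF file '", h@path, "' does not exist")
  invisible(h@path)
}

.root_attr_names <- c("title", "description", "creator", "contributor",
                      "created", "license", "rights", "tstart", "tend",
                      "software", "method", "nsdf_version")

#' Create (or reopen) an NSDF file for writing
#'
#' Creates an HDF5 file with the three level-1 groups `/data`, `/map` and
#' `/model` and writes the environment metadata as root attributes.  With
#' `overwrite = TRUE` (the default) an existing file of the same name is
#' replaced; with `overwrite = FALSE` an existing conforming file is opened
#' for appending and a non-NSDF file is rejected.
#'
#' @param path target file path
#' @param metadata an \linkS4class{NSDFMetadata} object
#' @param compression `"none"` or `"gzip"` (applied to every compressible
#'   dataset written through this handle; variable-length datasets cannot
#'   be compressed in HDF5 and are always stored raw)
#' @param level gzip compression level
#' @param overwrite replace an existing file?
#' @return an \linkS4class{NSDFFile} writer handle
#' @examples
#' f <- tempfile(fileext = ".h5")
#' h <- createNSDF(f, NSDFMetadata(title = "demo"))
#' @export
createNSDF <- function(path, metadata = NSDFMetadata(),
                       compression = c("none", "gzip"), level = 6L,
                       overwrite = TRUE) {
  compression <- match.arg(compression)
  stopifnot(is(metadata, "NSDFMetadata"))
  validObject(metadata)
  mode <- "create"
  if (file.exists(path) && !overwrite) {
    if (!rhdf5::H5Fis_hdf5(path) ||
        !all(vapply(c("/data", "/map"), .h5exists, logical(1L),
                    file = path)))
      stop("'", path, "' exists and is not an NSDF file; cannot append")
    return(new("NSDFFile", path = path, compression = compression,
               level = as.integer(level), mode = "append"))
  }
  if (file.exists(path)) unlink(path)
  if (!dir.exists(dirname(path)))
    stop("parent directory of '", path, "' does not exist")
  rhdf5::h5createFile(path)
  for (g in c("/data", "/map", "/map/time", "/model"))
    rhdf5::h5createGroup(path, g)
  for (nm in .root_attr_names) {
    v <- slot(metadata, nm)
    if (length(v) && any(nzchar(v))) .h5write_attr(path, "/", nm, v)
  }
  new("NSDFFile", path = path, compression = compression,
      level = as.integer(level), mode = mode)
}

#' Register the sources of a population as a dimension scale
#'
#' Stores the unique identifiers of a population's data sources as a 1D
#' string dataset under `/map/<category>/<population>` and marks it as a
#' dimension scale named `source`.  The scale is shared by all variables
#' recorded from the population; calling the function again with identical
#' uids returns the existing scale, while differing uids for the same
#' population are a conflict.
#'
#' @param h writer handle from [createNSDF()]
#' @param category one of static, uniform, nonuniform, event
#' @param population population name
#' @param uids nonempty character vector of unique source identifiers
#' @return the scale dataset path, invisibly
#' @export
addSourceScale <- function(h, category, population, uids) {
  file <- .check_handle(h)
  category <- match.arg(category, .categories)
  uids <- as.character(uids)
  if (!length(uids) || any(!nzchar(uids)))
    stop("'uids' must be a nonempty vector of nonempty strings")
  if (anyDuplicated(uids))
    stop("duplicate uids in source dimension scale")
  spath <- .scale_path(category, population)
  kind <- .h5kind(file, spath)
  if (identical(kind, "dataset")) {
    existing <- as.character(rhdf5::h5read(file, spath))
    if (identical(existing, uids)) return(invisible(spath))
    stop("population '", population, "' already has a '", category,
         "' source scale with different uids")
  }
  if (identical(kind, "group"))
    stop("'", spath, "' holds per-variable map tables (ONED variant); ",
         "it cannot also be a source dimension scale")
  .h5ensure_group(file, dirname(spath))
  .write_string_dataset(file, spath, uids)
  .ds_set_scale(file, spath, "source")
  invisible(spath)
}

# refuse to mix storage variants within one category of one file
.assert_variant_consistent <- function(h, category, variant) {
  file <- h@path
  base <- paste0("/data/", category)
  for (pop in .h5children(file, base)) {
    for (var in .h5children(file, paste0(base, "/", pop))) {
      v <- .detect_variant(file, category, pop, var)
      if (!is.na(v) && nzchar(v) && v != variant)
        stop("category '", category, "' already uses variant ", v,
             "; all arrays in one category must use a consistent variant")
    }
  }
  invisible(TRUE)
}

.check_unit <- function(unit, what = "unit", allowEmpty = FALSE) {
  if (!is.character(unit) || length(unit) < 1L || all(!nzchar(unit)) &&
      !allowEmpty)
    stop("a nonempty '", what, "' attribute is required")
  bad <- unit[nzchar(unit) & !isValidUnit(unit, allowEmpty = TRUE)]
  if (length(bad))
    warning("unit string(s) outside the supported grammar: ",
            paste(sQuote(bad), collapse = ", "))
  invisible(unit)
}

#' Write a uniformly sampled block
#'
#' Stores a \linkS4class{UniformBlock} as a 2D dataset under
#' `/data/uniform/<population>/<variable>` with the source scale attached
#' to the row dimension.  Timing is written either as `tstart`/`dt`/`tunit`
#' attributes (`timeMode = "attrs"`) or as an explicit time dimension scale
#' under `/map/time` (`timeMode = "explicit"`); when both descriptions end
#' up in a file, readers prefer the explicit scale.  The dataset is chunked
#' and extendible along time, so [appendUniform()] can grow it later.
#'
#' @param h writer handle
#' @param block a \linkS4class{UniformBlock}
#' @param timeMode `"attrs"` or `"explicit"`
#' @return the dataset path, invisibly
#' @export
addUniform <- function(h, block, timeMode = c("attrs", "explicit")) {
  file <- .check_handle(h)
  timeMode <- match.arg(timeMode)
  stopifnot(is(block, "UniformBlock"))
  validObject(block)
  .check_unit(block@unit)
  .check_unit(block@tunit, "tunit")
  pop <- block@population; var <- block@variable
  dpath <- .data_path("uniform", pop, var)
  if (.h5exists(file, dpath))
    stop("'", dpath, "' already exists; use appendUniform() to extend it")
  P <- nrow(block@values); Q <- ncol(block@values)
  tstart <- block@tstart; dt <- block@dt
  tt <- NULL
  if (length(block@explicitTimes)) {
    tt <- block@explicitTimes
    if (!is.na(dt)) {
      comp <- uniformTimeAxis(tstart, dt, Q)
      tol <- 1e-12 * max(1, abs(comp))
      if (any(abs(comp - tt) > tol))
        stop("explicit time axis disagrees with tstart/dt; ",
             "refusing to write an inconsistent pair")
    } else if (Q > 1L) {
      dd <- diff(tt)
      if (max(dd) - min(dd) <= 1e-9 * max(dd)) {
        dt <- stats::median(dd); tstart <- tt[1L]
      }
    }
  } else if (timeMode == "explicit") {
    tt <- uniformTimeAxis(tstart, dt, Q)
  }
  spath <- addSourceScale(h, "uniform", pop, block@sources)
  .h5ensure_group(file, dirname(dpath))
  .create_matrix_dataset(file, dpath, P, Q, h@compression, h@level,
                         extendible = TRUE)
  .write_matrix(file, dpath, block@values)
  .h5write_attr(file, dpath, "unit", block@unit)
  .h5write_attr(file, dpath, "field", block@field)
  .h5write_attr(file, dpath, "tunit", block@tunit)
  if (!is.na(dt)) {
    .h5write_attr(file, dpath, "tstart", as.numeric(tstart))
    .h5write_attr(file, dpath, "dt", as.numeric(dt))
  }
  if (timeMode == "explicit") {
    if (is.null(tt)) stop("no time axis available for explicit mode")
    tpath <- .time_path("uniform", pop, var)
    .write_vector_dataset(file, tpath, tt, h@compression, h@level,
                          extendible = TRUE)
    .h5write_attr(file, tpath, "unit", block@tunit)
    .ds_set_scale(file, tpath, "time")
    .ds_attach(file, dpath, tpath, 1L, "time")
  }
  .ds_attach(file, dpath, spath, 0L, "source")
  invisible(dpath)
}

#' Append columns to a uniform dataset
#'
#' Extends an existing uniform dataset along the time dimension without
#' touching previously written values or the `tstart`/`dt` attributes.
#' When the dataset carries an explicit time scale, matching new sampling
#' times must be supplied.
#'
#' @param h writer handle
#' @param population,variable address of the dataset
#' @param newColumns P x K matrix (or length-P vector for K = 1) of new
#'   samples
#' @param times length-K vector of new sampling times; required if (and
#'   only if) the dataset has an explicit time scale
#' @return the new total number of columns, invisibly
#' @export
appendUniform <- function(h, population, variable, newColumns,
                          times = NULL) {
  file <- .check_handle(h)
  dpath <- .data_path("uniform", population, variable)
  if (!.h5exists(file, dpath)) stop("no such uniform dataset: ", dpath)
  d <- .dset_dims(file, dpath)
  P <- d[1L]; Q <- d[2L]
  if (!is.matrix(newColumns)) {
    if (length(newColumns) %% max(P, 1L) != 0L)
      stop("new columns must have ", P, " rows")
    newColumns <- matrix(as.numeric(newColumns), nrow = P)
  }
  if (nrow(newColumns) != P)
    stop("row count of new columns (", nrow(newColumns),
         ") does not match the dataset (", P, ")")
  K <- ncol(newColumns)
  tscales <- .ds_scales(file, dpath, 1L)
  if (K == 0L) return(invisible(Q))
  if (length(tscales)) {
    if (is.null(times))
      stop("dataset has an explicit time scale; supply matching 'times'")
    if (length(times) != K)
      stop("'times' must have one entry per appended column")
  }
  rhdf5::h5set_extent(file, dpath, c(Q + K, P))
  .write_matrix(file, dpath, newColumns, colOffset = Q)
  for (ts in tscales) .append_vector_dataset(file, ts, times)
  invisible(Q + K)
}

## ragged writing core (events and general nonuniform) ----------------------

.write_ragged <- function(h, category, pop, var, srcs, valuesRows,
                          timesRows, unit, field, tunit, variant,
                          extendible = FALSE, checkConsistency = TRUE) {
  file <- h@path
  dpath <- .data_path(category, pop, var)
  if (.h5exists(file, dpath)) stop("'", dpath, "' already exists")
  if (checkConsistency) .assert_variant_consistent(h, category, variant)
  if (variant == "VLEN") {
    .h5ensure_group(file, dirname(dpath))
    .vlen_write(file, dpath, valuesRows)
    spath <- addSourceScale(h, category, pop, srcs)
    if (!is.null(timesRows)) {
      tpath <- .time_path(category, pop, var)
      .vlen_write(file, tpath, timesRows)
      .h5write_attr(file, tpath, "unit", tunit)
      .ds_set_scale(file, tpath, "time")
      .ds_attach(file, dpath, tpath, 0L, "time")
    }
    .ds_attach(file, dpath, spath, 0L, "source")
    .h5write_attr(file, dpath, "unit", unit)
    .h5write_attr(file, dpath, "field", field)
    return(invisible(dpath))
  }
  if (variant == "NANPADDED") {
    mat <- nanPad(valuesRows)
    .h5ensure_group(file, dirname(dpath))
    .create_matrix_dataset(file, dpath, nrow(mat), ncol(mat),
                           h@compression, h@level, extendible = extendible,
                           fillValue = NaN)
    .write_matrix(file, dpath, mat)
    spath <- addSourceScale(h, category, pop, srcs)
    if (!is.null(timesRows)) {
      tmat <- nanPad(timesRows)
      tpath <- .time_path(category, pop, var)
      .create_matrix_dataset(file, tpath, nrow(tmat), ncol(tmat),
                             h@compression, h@level,
                             extendible = extendible, fillValue = NaN)
      .write_matrix(file, tpath, tmat)
      .h5write_attr(file, tpath, "unit", tunit)
      .ds_set_scale(file, tpath, "time")
      .ds_attach(file, dpath, tpath, 1L, "time")
    }
    .ds_attach(file, dpath, spath, 0L, "source")
    .h5write_attr(file, dpath, "unit", unit)
    .h5write_attr(file, dpath, "field", field)
    return(invisible(dpath))
  }
  ## ONED: one 1D dataset per source at level 5 plus a source/data map table
  tbl <- .table_path(category, pop, var)
  if (identical(.h5kind(file, dirname(tbl)), "dataset"))
    stop("'", dirname(tbl), "' is a source dimension scale; the ONED map ",
         "table layout conflicts with it")
  .h5ensure_group(file, dpath)
  nms <- .oned_names(srcs)
  paths <- file.path(dpath, nms)
  for (i in seq_along(srcs)) {
    .write_vector_dataset(file, paths[i], valuesRows[[i]], h@compression,
                          h@level, extendible = extendible)
    .h5write_attr(file, paths[i], "source", srcs[i])
    .h5write_attr(file, paths[i], "unit", unit)
    .h5write_attr(file, paths[i], "field", field)
    if (!is.null(timesRows)) {
      tpath <- .time_path(category, pop, var, i - 1L)
      .write_vector_dataset(file, tpath, timesRows[[i]], h@compression,
                            h@level, extendible = extendible)
      .h5write_attr(file, tpath, "unit", tunit)
      .ds_set_scale(file, tpath, "time")
      .ds_attach(file, paths[i], tpath, 0L, "time")
    }
  }
  .h5ensure_group(file, dirname(tbl))
  if (.h5exists(file, tbl)) rhdf5::h5delete(file, tbl)
  rhdf5::h5write(data.frame(source = srcs, data = paths,
                            stringsAsFactors = FALSE), file, tbl)
  .h5write_attr(file, dpath, "map", tbl)
  .h5write_attr(file, dpath, "unit", unit)
  .h5write_attr(file, dpath, "field", field)
  invisible(dpath)
}

#' Write an event (spike-time) set
#'
#' Stores an \linkS4class{EventSet} under `/data/event` in one of the three
#' ragged storage variants: `ONED` (one 1D dataset per source plus a
#' two-field source/data map table referenced from the variable group),
#' `VLEN` (a single ragged dataset with the source scale attached) or
#' `NANPADDED` (a regular 2D dataset padded with trailing NaN).  The
#' NUREGULAR variant is not applicable to events.  All variables of one
#' category in a file must use the same variant.
#'
#' @param h writer handle
#' @param events an \linkS4class{EventSet}
#' @param variant `"VLEN"`, `"ONED"` or `"NANPADDED"`
#' @param extendible create per-source/2D datasets chunked and extendible
#'   so that [appendEvents()] can grow them (VLEN rows are always
#'   rewritable)
#' @return the written variable path, invisibly
#' @export
addEvents <- function(h, events, variant = c("VLEN", "ONED", "NANPADDED"),
                      extendible = FALSE) {
  .check_handle(h)
  variant <- as.character(variant)[1L]
  if (variant == "NUREGULAR")
    stop("the NUREGULAR variant is not applicable for event data")
  variant <- match.arg(variant, c("VLEN", "ONED", "NANPADDED"))
  stopifnot(is(events, "EventSet"))
  validObject(events)
  .check_unit(events@unit)
  .write_ragged(h, "event", events@population, events@variable,
                events@sources, events@times, NULL, events@unit,
                events@field, NULL, variant, extendible)
}

#' Write a nonuniformly sampled series
#'
#' Stores a \linkS4class{RaggedSeries} under `/data/nonuniform`.  When all
#' sources share one sampling-time axis the `NUREGULAR` variant stores a
#' regular 2D dataset with a shared 1D time scale under `/map/time`; the
#' ragged variants (`ONED`, `VLEN`, `NANPADDED`) store per-source
#' sampling-time arrays under `/map/time` in the matching shape (1D per
#' source, ragged, or congruently NaN-padded).
#'
#' @param h writer handle
#' @param series a \linkS4class{RaggedSeries}
#' @param variant one of NUREGULAR, ONED, VLEN, NANPADDED
#' @param extendible as in [addEvents()]
#' @return the written variable path, invisibly
#' @export
addNonuniform <- function(h, series,
                          variant = c("NUREGULAR", "ONED", "VLEN",
                                      "NANPADDED"),
                          extendible = FALSE) {
  file <- .check_handle(h)
  variant <- match.arg(variant)
  stopifnot(is(series, "RaggedSeries"))
  validObject(series)
  .check_unit(series@unit)
  pop <- series@population; var <- series@variable
  if (variant == "NUREGULAR") {
    if (!length(series@sharedTimes))
      stop("NUREGULAR storage requires a shared sampling-time axis")
    .assert_variant_consistent(h, "nonuniform", "NUREGULAR")
    dpath <- .data_path("nonuniform", pop, var)
    if (.h5exists(file, dpath)) stop("'", dpath, "' already exists")
    mat <- do.call(rbind, series@values)
    spath <- addSourceScale(h, "nonuniform", pop, series@sources)
    .h5ensure_group(file, dirname(dpath))
    .create_matrix_dataset(file, dpath, nrow(mat), ncol(mat),
                           h@compression, h@level, extendible = extendible)
    .write_matrix(file, dpath, mat)
    tpath <- .time_path("nonuniform", pop, var)
    .write_vector_dataset(file, tpath, series@sharedTimes, h@compression,
                          h@level, extendible = extendible)
    .h5write_attr(file, tpath, "unit", series@tunit)
    .ds_set_scale(file, tpath, "time")
    .ds_attach(file, dpath, tpath, 1L, "time")
    .ds_attach(file, dpath, spath, 0L, "source")
    .h5write_attr(file, dpath, "unit", series@unit)
    .h5write_attr(file, dpath, "field", series@field)
    return(invisible(dpath))
  }
  .write_ragged(h, "nonuniform", pop, var, series@sources, series@values,
                times(series), series@unit, series@field, series@tunit,
                variant, extendible)
}

#' Append new events or samples to a ragged variable
#'
#' Extends an existing event or nonuniform variable, whatever its storage
#' variant: ONED datasets are extended in place, VLEN rows are rewritten
#' with the concatenated arrays, NANPADDED matrices grow in width with NaN
#' fill.  New per-source times must not precede already stored ones.
#'
#' @param h writer handle
#' @param events an \linkS4class{EventSet} holding the new events (sources
#'   must be a subset of the stored ones)
#' @return invisibly, the new per-source array lengths
#' @export
appendEvents <- function(h, events) {
  stopifnot(is(events, "EventSet"))
  validObject(events)
  .append_ragged(h, "event", events@population, events@variable,
                 events@sources, events@times, NULL)
}

#' @rdname appendEvents
#' @param series a \linkS4class{RaggedSeries} with the new samples and
#'   their sampling times
#' @export
appendNonuniform <- function(h, series) {
  stopifnot(is(series, "RaggedSeries"))
  validObject(series)
  .append_ragged(h, "nonuniform", series@population, series@variable,
                 series@sources, series@values, times(series))
}

.append_ragged <- function(h, category, pop, var, srcs, valuesRows,
                           timesRows) {
  file <- .check_handle(h)
  dpath <- .data_path(category, pop, var)
  if (!.h5exists(file, dpath)) stop("no such variable: ", dpath)
  variant <- .detect_variant(file, category, pop, var)
  if (variant == "ONED") {
    tbl <- as.character(.h5attrs(file, dpath)$map)
    map <- rhdf5::h5read(file, tbl)
    map$source <- as.character(map$source)
    map$data <- as.character(map$data)
    idx <- match(srcs, map$source)
    if (anyNA(idx)) stop("unknown source(s): ",
                         paste(srcs[is.na(idx)], collapse = ", "))
    lens <- integer(length(srcs))
    for (k in seq_along(srcs)) {
      ds <- map$data[idx[k]]
      lens[k] <- .append_vector_dataset(file, ds, valuesRows[[k]])
      if (!is.null(timesRows)) {
        tsc <- .ds_scales(file, ds, 0L)
        tsc <- tsc[startsWith(tsc, "/map/time/")]
        if (length(tsc) != 1L)
          stop("cannot locate the time scale of ", ds)
        .append_vector_dataset(file, tsc, timesRows[[k]])
      }
    }
    return(invisible(lens))
  }
  scale <- .source_scale_of(file, dpath)
  stored <- as.character(rhdf5::h5read(file, scale))
  idx <- match(srcs, stored)
  if (anyNA(idx)) stop("unknown source(s): ",
                       paste(srcs[is.na(idx)], collapse = ", "))
  if (variant == "VLEN") {
    cur <- .vlen_read(file, dpath)
    tpath <- .time_path(category, pop, var)
    curT <- if (!is.null(timesRows)) .vlen_read(file, tpath)
    lens <- integer(length(srcs))
    for (k in seq_along(srcs)) {
      i <- idx[k]
      .vlen_write_row(file, dpath, i - 1L, c(cur[[i]], valuesRows[[k]]))
      lens[k] <- length(cur[[i]]) + length(valuesRows[[k]])
      if (!is.null(timesRows))
        .vlen_write_row(file, tpath, i - 1L, c(curT[[i]], timesRows[[k]]))
    }
    return(invisible(lens))
  }
  ## NANPADDED
  d <- .dset_dims(file, dpath)
  mat <- .read_matrix(file, dpath)
  curLens <- .nan_row_lengths(mat)
  newLens <- curLens
  newLens[idx] <- curLens[idx] + lengths(valuesRows)
  W <- max(d[2L], max(newLens))
  if (W > d[2L]) {
    rhdf5::h5set_extent(file, dpath, c(W, d[1L]))
    if (!is.null(timesRows)) {
      tpath <- .time_path(category, pop, var)
      rhdf5::h5set_extent(file, tpath, c(W, d[1L]))
    }
  }
  for (k in seq_along(srcs)) {
    i <- idx[k]
    kk <- length(valuesRows[[k]])
    if (!kk) next
    cols <- curLens[i] + seq_len(kk)
    rhdf5::h5write(as.numeric(valuesRows[[k]]), file, dpath,
                   index = list(cols, i))
    if (!is.null(timesRows))
      rhdf5::h5write(as.numeric(timesRows[[k]]), file,
                     .time_path(category, pop, var), index = list(cols, i))
  }
  invisible(newLens[idx])
}

#' Write a static table
#'
#' Stores a \linkS4class{StaticTable} under `/data/static`: homogeneous
#' numeric tables become a 2D dataset with the source scale on rows and a
#' column-label scale (labelled `field`) on columns; record-style tables
#' become an HDF5 compound dataset whose `unit` attribute is the array of
#' per-field unit strings (empty for non-physical fields such as indices).
#'
#' @param h writer handle
#' @param table a \linkS4class{StaticTable}
#' @return the dataset path, invisibly
#' @export
addStatic <- function(h, table) {
  file <- .check_handle(h)
  stopifnot(is(table, "StaticTable"))
  validObject(table)
  .check_unit(table@units, allowEmpty = table@layout == "COMPOUND")
  pop <- table@population
  dpath <- .data_path("static", pop, table@name)
  if (.h5exists(file, dpath)) stop("'", dpath, "' already exists")
  spath <- addSourceScale(h, "static", pop, table@sources)
  .h5ensure_group(file, dirname(dpath))
  if (table@layout == "HOMOGENEOUS_2D") {
    mat <- as.matrix(table@data)
    storage.mode(mat) <- "double"
    .create_matrix_dataset(file, dpath, nrow(mat), ncol(mat),
                           h@compression, h@level)
    .write_matrix(file, dpath, mat)
    lpath <- sprintf("/map/static/%s_%s_fields", pop, table@name)
    .write_string_dataset(file, lpath, colnames(table@data))
    .ds_set_scale(file, lpath, "field")
    .ds_attach(file, dpath, lpath, 1L, "field")
  } else {
    rhdf5::h5write(table@data, file, dpath)
  }
  .ds_attach(file, dpath, spath, 0L, "source")
  .h5write_attr(file, dpath, "unit", table@units)
  .h5write_attr(file, dpath, "field", table@name)
  invisible(dpath)
}

## model description ---------------------------------------------------------

#' Store the fallback hierarchical model description
#'
#' Writes a \linkS4class{ModelNode} tree under `/model/modeltree`, one HDF5
#' group per component, carrying the `uid`, optional `ontology`, free-form
#' attributes and - for components with recorded data - a `map` attribute
#' listing the paths of the mapping datasets under `/map`.  Repeated calls
#' add further root components (a model forest).
#'
#' @param h writer handle
#' @param root a \linkS4class{ModelNode}
#' @return the group path of the written root, invisibly
#' @export
addModelTree <- function(h, root) {
  file <- .check_handle(h)
  stopifnot(is(root, "ModelNode"))
  uids <- character()
  collect <- function(n) {
    validObject(n)
    uids <<- c(uids, n@uid)
    nm <- vapply(n@children, function(ch) ch@name, character(1L))
    if (anyDuplicated(nm))
      stop("duplicate sibling component names under '", n@name, "'")
    for (ch in n@children) collect(ch)
  }
  collect(root)
  if (anyDuplicated(uids))
    stop("duplicate uid(s) in model tree: ",
         paste(unique(uids[duplicated(uids)]), collapse = ", "))
  if (.h5exists(file, "/model/modeltree")) {
    existing <- .modeltree_uids(file)
    clash <- intersect(existing, uids)
    if (length(clash))
      stop("uid(s) already present in the file's model tree: ",
           paste(clash, collapse = ", "))
  }
  .h5ensure_group(file, "/model/modeltree")
  write_node <- function(n, parent) {
    g <- paste0(parent, "/", n@name)
    if (.h5exists(file, g))
      stop("model component '", g, "' already exists")
    rhdf5::h5createGroup(file, g)
    .h5write_attr(file, g, "uid", n@uid)
    if (length(n@ontology)) .h5write_attr(file, g, "ontology", n@ontology)
    for (a in names(n@attributes))
      .h5write_attr(file, g, a, unname(n@attributes[a]))
    if (length(n@mapRefs)) .h5write_attr(file, g, "map", n@mapRefs)
    for (ch in n@children) write_node(ch, g)
    g
  }
  invisible(write_node(root, "/model/modeltree"))
}

#' Embed, reference or link external model descriptions
#'
#' `addFileContents()` replicates model files inside the NSDF file: each
#' relative path becomes a chain of groups under `/model/filecontents`
#' ending in a string dataset holding the file text.  `addFileRefs()`
#' records external file paths in the string dataset
#' `/model/filerefs/files`.  `addExternalLinks()` creates HDF5 external
#' links under `/model/links` to nodes of other HDF5 files.
#'
#' @param h writer handle
#' @param files named list or character vector: relative path -> file text
#' @return the group path written to, invisibly
#' @export
addFileContents <- function(h, files) {
  file <- .check_handle(h)
  stopifnot(length(files) > 0L, !is.null(names(files)))
  paths <- names(files)
  if (any(startsWith(paths, "/")))
    stop("filecontents paths must be relative (portability)")
  if (any(vapply(strsplit(paths, "/", fixed = TRUE),
                 function(p) any(p %in% c("..", "")), logical(1L))))
    stop("filecontents paths must not contain '..' or empty components")
  .h5ensure_group(file, "/model/filecontents")
  for (p in paths) {
    full <- paste0("/model/filecontents/", p)
    .h5ensure_group(file, dirname(full))
    .write_string_dataset(file, full, as.character(files[[p]]))
  }
  invisible("/model/filecontents")
}

#' @rdname addFileContents
#' @param paths character vector of external model-file paths or URLs
#' @export
addFileRefs <- function(h, paths) {
  file <- .check_handle(h)
  stopifnot(is.character(paths), length(paths) > 0L)
  .h5ensure_group(file, "/model/filerefs")
  ds <- "/model/filerefs/files"
  if (.h5exists(file, ds))
    paths <- c(as.character(rhdf5::h5read(file, ds)), paths)
  .write_string_dataset(file, ds, paths)
  invisible("/model/filerefs")
}

#' @rdname addFileContents
#' @param links named list; each element is `c(file = <hdf5 file>,
#'   path = <object path within it>)`
#' @export
addExternalLinks <- function(h, links) {
  file <- .check_handle(h)
  stopifnot(length(links) > 0L, !is.null(names(links)))
  .h5ensure_group(file, "/model/links")
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid))
  gid <- rhdf5::H5Gopen(fid, "/model/links")
  on.exit(rhdf5::H5Gclose(gid), add = TRUE, after = FALSE)
  for (nm in names(links)) {
    tgt <- links[[nm]]
    rhdf5::H5Lcreate_external(tgt[["file"]], tgt[["path"]], gid, nm)
  }
  invisible("/model/links")
}
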