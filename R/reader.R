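# Reader: indexes an NSDF file, detects the storage variant of every
# variable, reconstructs the in-memory containers (including time axes) and
# resolves source mappings in both directions.

# classify the scales attached to dimension `dim` of a dataset
.scales_by_class <- function(file, dpath, dim) {
  sc <- .ds_scales(file, dpath, dim)
  if (!length(sc))
    return(list(string = character(), float1d = character(),
                float2d = character(), vlen = character()))
  cls <- vapply(sc, .dtype_class, character(1L), file = file)
  rank <- vapply(sc, function(p) length(.dset_dims(file, p)), integer(1L))
  list(string = sc[cls == "string"],
       float1d = sc[cls == "float" & rank == 1L],
       float2d = sc[cls == "float" & rank == 2L],
       vlen = sc[cls == "vlen"])
}

.source_scale_of <- function(file, dpath) {
  sc <- .scales_by_class(file, dpath, 0L)
  if (!length(sc$string))
    stop("broken mapping: no source dimension scale attached to ", dpath)
  sc$string[[1L]]
}

# storage variant of one variable node; "" for the variant-free categories,
# NA for unrecognisable layouts
.detect_variant <- function(file, cat, pop, var) {
  node <- .data_path(cat, pop, var)
  kind <- .h5kind(file, node)
  if (identical(kind, "group"))
    return(if (cat %in% c("nonuniform", "event")) "ONED" else NA_character_)
  if (!identical(kind, "dataset")) return(NA_character_)
  if (cat %in% c("uniform", "static")) return("")
  cls <- .dtype_class(file, node)
  if (cls == "vlen") return("VLEN")
  rank <- length(.dset_dims(file, node))
  if (rank != 2L) return(NA_character_)
  if (cat == "event") return("NANPADDED")
  sc <- .scales_by_class(file, node, 1L)
  if (length(sc$float2d) || length(sc$vlen)) return("NANPADDED")
  vals <- .read_matrix(file, node)
  if (anyNA(vals)) return("NANPADDED")
  "NUREGULAR"
}

.modeltree_uids <- function(file) {
  out <- character()
  rec <- function(g) {
    for (ch in .h5children(file, g)) {
      p <- paste0(g, "/", ch)
      if (identical(.h5kind(file, p), "group")) {
        a <- .h5attrs(file, p)
        if (!is.null(a$uid)) out <<- c(out, as.character(a$uid))
        rec(p)
      }
    }
  }
  rec("/model/modeltree")
  out
}

#' Open and index an NSDF file
#'
#' Enumerates every population and variable under `/data`, detects the
#' storage variant of each ragged variable from the layout alone (a group
#' of 1D datasets with a map table is ONED, a ragged dataset VLEN, a 2D
#' dataset with NaN padding or a padded time matrix NANPADDED, a regular
#' 2D nonuniform dataset with a shared 1D time scale NUREGULAR), and notes
#' which model-description kinds are present.  Layouts that fit no variant
#' are reported in the index's `issues`, not raised as errors.
#'
#' @param path an NSDF/HDF5 file
#' @return an \linkS4class{NSDFIndex}
#' @examples
#' f <- tempfile(fileext = ".h5")
#' writeBundle(genTwoNeurons(seed = 0), f)
#' openNSDF(f)
#' @export
openNSDF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!isTRUE(rhdf5::H5Fis_hdf5(path)))
    stop("'", path, "' is not an HDF5 file")
  if (!.h5exists(path, "/data"))
    stop("'", path, "' is not an NSDF file: missing /data group")
  issues <- character()
  rows <- list()
  for (cat in .h5children(path, "/data")) {
    if (!cat %in% .categories) {
      issues <- c(issues,
                  sprintf("unknown category group '/data/%s'", cat))
      next
    }
    for (pop in .h5children(path, paste0("/data/", cat))) {
      for (var in .h5children(path, sprintf("/data/%s/%s", cat, pop))) {
        v <- .detect_variant(path, cat, pop, var)
        if (is.na(v)) {
          issues <- c(issues, sprintf(
            "unrecognisable layout at /data/%s/%s/%s", cat, pop, var))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          category = cat, population = pop, variable = var, variant = v,
          path = .data_path(cat, pop, var), stringsAsFactors = FALSE)
      }
    }
  }
  ds <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), population = character(),
               variable = character(), variant = character(),
               path = character(), stringsAsFactors = FALSE)
  kinds <- intersect(c("modeltree", "filecontents", "filerefs", "links"),
                     .h5children(path, "/model"))
  new("NSDFIndex", path = path, datasets = ds, modelKinds = kinds,
      issues = issues)
}

.index_row <- function(ix, category, population, variable) {
  d <- ix@datasets
  i <- which(d$category == category & d$population == population &
             d$variable == variable)
  if (!length(i))
    stop("no ", category, " variable '", population, "/", variable,
         "' in ", ix@path)
  d[i[1L], ]
}

.attr1 <- function(a, name, default = NA) {
  v <- a[[name]]
  if (is.null(v) || !length(v)) default else v[[1L]]
}

#' Read a uniformly sampled block
#'
#' Reconstructs a \linkS4class{UniformBlock}: the value matrix, the source
#' uids from the attached scale, and the time axis.  When an explicit time
#' scale is attached it takes precedence over the `tstart`/`dt` attributes
#' (a warning is emitted if the two descriptions disagree); with neither
#' present the dataset's timing is incomplete and an error is raised.
#'
#' @param ix an \linkS4class{NSDFIndex} from [openNSDF()]
#' @param population,variable address of the variable
#' @return a \linkS4class{UniformBlock}
#' @export
readUniform <- function(ix, population, variable) {
  stopifnot(is(ix, "NSDFIndex"))
  row <- .index_row(ix, "uniform", population, variable)
  file <- ix@path; dpath <- row$path
  a <- .h5attrs(file, dpath)
  srcs <- as.character(rhdf5::h5read(file, .source_scale_of(file, dpath)))
  vals <- .read_matrix(file, dpath)
  tsc <- .scales_by_class(file, dpath, 1L)$float1d
  tstart <- as.numeric(.attr1(a, "tstart", NA_real_))
  dt <- as.numeric(.attr1(a, "dt", NA_real_))
  expl <- numeric()
  if (length(tsc)) {
    expl <- as.numeric(rhdf5::h5read(file, tsc[[1L]]))
    if (!is.na(dt) && ncol(vals) > 0L) {
      comp <- uniformTimeAxis(tstart, dt, ncol(vals))
      if (max(abs(comp - expl)) > 1e-9 * max(1, abs(expl)))
        warning("tstart/dt attributes disagree with the explicit time ",
                "scale of ", dpath, "; the scale takes precedence")
    }
    tstart <- expl[1L]; dt <- NA_real_
  } else if (is.na(tstart) || is.na(dt)) {
    stop("incomplete metadata: ", dpath,
         " has neither tstart/dt attributes nor a time dimension scale")
  }
  UniformBlock(population, variable, srcs, vals,
               unit = as.character(.attr1(a, "unit", "")),
               field = as.character(.attr1(a, "field", variable)),
               tstart = if (is.na(tstart)) 0 else tstart, dt = dt,
               tunit = as.character(.attr1(a, "tunit", "s")),
               explicitTimes = expl)
}

#' Read a column range of a uniform dataset
#'
#' Streams the half-open 0-based column range `[from, to)` of a uniform
#' dataset without loading the rest, with the time axis offset accordingly;
#' concatenating consecutive ranges reproduces the full read.
#'
#' @inheritParams readUniform
#' @param from,to 0-based half-open column range, `0 <= from <= to <= Q`
#' @return a \linkS4class{UniformBlock} with `to - from` columns
#' @export
readColumnRange <- function(ix, population, variable, from, to) {
  stopifnot(is(ix, "NSDFIndex"))
  row <- .index_row(ix, "uniform", population, variable)
  file <- ix@path; dpath <- row$path
  Q <- .dset_dims(file, dpath)[2L]
  from <- as.integer(from); to <- as.integer(to)
  if (is.na(from) || is.na(to) || from < 0L || to < from || to > Q)
    stop("column range [", from, ", ", to, ") out of bounds for Q = ", Q)
  a <- .h5attrs(file, dpath)
  srcs <- as.character(rhdf5::h5read(file, .source_scale_of(file, dpath)))
  cols <- if (from == to) integer() else (from + 1L):to
  vals <- .read_matrix(file, dpath, cols = cols)
  tsc <- .scales_by_class(file, dpath, 1L)$float1d
  tstart <- as.numeric(.attr1(a, "tstart", NA_real_))
  dt <- as.numeric(.attr1(a, "dt", NA_real_))
  expl <- numeric()
  if (length(tsc)) {
    expl <- if (length(cols))
      as.numeric(rhdf5::h5read(file, tsc[[1L]], index = list(cols))) else
      numeric()
    tstart <- if (length(expl)) expl[1L] else 0
    dt <- NA_real_
  } else if (is.na(tstart) || is.na(dt)) {
    stop("incomplete metadata: ", dpath,
         " has neither tstart/dt attributes nor a time dimension scale")
  } else {
    tstart <- tstart + from * dt
  }
  UniformBlock(population, variable, srcs, vals,
               unit = as.character(.attr1(a, "unit", "")),
               field = as.character(.attr1(a, "field", variable)),
               tstart = tstart, dt = dt,
               tunit = as.character(.attr1(a, "tunit", "s")),
               explicitTimes = expl)
}

# read an ONED map table as a data.frame with character columns
.read_map_table <- function(file, tbl) {
  map <- rhdf5::h5read(file, tbl)
  data.frame(source = as.character(map$source),
             data = as.character(map$data), stringsAsFactors = FALSE)
}

# locate the ONED map table of a variable group: `map` attribute first,
# deterministic path as fallback
.oned_table <- function(file, cat, pop, var) {
  a <- .h5attrs(file, .data_path(cat, pop, var))
  tbl <- as.character(.attr1(a, "map", ""))
  if (!nzchar(tbl)) tbl <- .table_path(cat, pop, var)
  if (!.h5exists(file, tbl))
    stop("broken mapping: no source/data map table for ",
         .data_path(cat, pop, var))
  tbl
}

.read_ragged_rows <- function(file, cat, pop, var, variant, withTimes) {
  dpath <- .data_path(cat, pop, var)
  if (variant == "ONED") {
    tbl <- .oned_table(file, cat, pop, var)
    map <- .read_map_table(file, tbl)
    a <- .h5attrs(file, dpath)
    vals <- vector("list", nrow(map))
    tms <- if (withTimes) vector("list", nrow(map))
    for (i in seq_len(nrow(map))) {
      ds <- map$data[i]
      if (!.h5exists(file, ds))
        stop("broken mapping: map table row for '", map$source[i],
             "' points to missing dataset ", ds)
      vals[[i]] <- as.numeric(rhdf5::h5read(file, ds))
      if (withTimes) {
        tsc <- .scales_by_class(file, ds, 0L)$float1d
        if (!length(tsc))
          stop("no sampling-time scale attached to ", ds)
        tms[[i]] <- as.numeric(rhdf5::h5read(file, tsc[[1L]]))
      }
      if (i == 1L && is.null(a$unit))
        a <- .h5attrs(file, ds)
    }
    return(list(sources = map$source, values = vals, times = tms,
                unit = as.character(.attr1(a, "unit", "")),
                field = as.character(.attr1(a, "field", var))))
  }
  a <- .h5attrs(file, dpath)
  srcs <- as.character(rhdf5::h5read(file, .source_scale_of(file, dpath)))
  if (variant == "VLEN") {
    vals <- .vlen_read(file, dpath)
    tms <- NULL
    if (withTimes) {
      tsc <- .scales_by_class(file, dpath, 0L)$vlen
      if (!length(tsc))
        stop("no ragged sampling-time scale attached to ", dpath)
      tms <- .vlen_read(file, tsc[[1L]])
      if (!identical(lengths(tms), lengths(vals)))
        stop("congruence error: per-source value and time lengths differ ",
             "in ", dpath)
    }
  } else {                              # NANPADDED
    mat <- .read_matrix(file, dpath)
    vals <- nanUnpad(mat)
    tms <- NULL
    if (withTimes) {
      sc1 <- .scales_by_class(file, dpath, 1L)
      if (!length(sc1$float2d))
        stop("no NaN-padded sampling-time matrix attached to ", dpath)
      tmat <- .read_matrix(file, sc1$float2d[[1L]])
      if (!identical(is.na(mat), is.na(tmat)))
        stop("congruence error: NaN masks of values and times differ in ",
             dpath)
      tms <- nanUnpad(tmat)
    }
  }
  list(sources = srcs, values = vals, times = tms,
       unit = as.character(.attr1(a, "unit", "")),
       field = as.character(.attr1(a, "field", var)))
}

#' Read an event set, whatever its storage variant
#'
#' Returns a variant-independent \linkS4class{EventSet}: ONED files are
#' resolved through the source/data map table (row order preserved), VLEN
#' and NANPADDED files through the source scale, with NaN padding stripped.
#' A source with zero events yields an empty vector, not an absent entry.
#'
#' @inheritParams readUniform
#' @return an \linkS4class{EventSet}
#' @export
readEvents <- function(ix, population, variable) {
  stopifnot(is(ix, "NSDFIndex"))
  row <- .index_row(ix, "event", population, variable)
  r <- .read_ragged_rows(ix@path, "event", population, variable,
                         row$variant, withTimes = FALSE)
  EventSet(population, variable, r$sources, r$values,
           unit = if (nzchar(r$unit)) r$unit else "s", field = r$field)
}

#' Read a nonuniformly sampled series, whatever its storage variant
#'
#' NUREGULAR files return the shared sampling-time axis; the ragged
#' variants return congruent per-source value and time vectors (the NaN
#' masks of a NANPADDED pair must match, and VLEN row lengths must agree).
#'
#' @inheritParams readUniform
#' @return a \linkS4class{RaggedSeries}
#' @export
readNonuniform <- function(ix, population, variable) {
  stopifnot(is(ix, "NSDFIndex"))
  row <- .index_row(ix, "nonuniform", population, variable)
  file <- ix@path
  if (row$variant == "NUREGULAR") {
    dpath <- row$path
    a <- .h5attrs(file, dpath)
    srcs <- as.character(rhdf5::h5read(file, .source_scale_of(file, dpath)))
    vals <- .read_matrix(file, dpath)
    tsc <- .scales_by_class(file, dpath, 1L)$float1d
    if (!length(tsc))
      stop("no shared time scale attached to NUREGULAR dataset ", dpath)
    shared <- as.numeric(rhdf5::h5read(file, tsc[[1L]]))
    tunit <- as.character(.attr1(.h5attrs(file, tsc[[1L]]), "unit", "s"))
    return(RaggedSeries(population, variable, srcs,
                        values = lapply(seq_len(nrow(vals)),
                                        function(i) vals[i, ]),
                        sharedTimes = shared,
                        unit = as.character(.attr1(a, "unit", "")),
                        field = as.character(.attr1(a, "field", variable)),
                        tunit = tunit))
  }
  r <- .read_ragged_rows(file, "nonuniform", population, variable,
                         row$variant, withTimes = TRUE)
  RaggedSeries(population, variable, r$sources, values = r$values,
               times = r$times, unit = r$unit, field = r$field)
}

#' Read a static table
#'
#' Record-style datasets come back as COMPOUND tables with their per-field
#' unit array; plain 2D datasets as HOMOGENEOUS_2D tables with column
#' labels recovered from the `field` label scale when present.
#'
#' @inheritParams readUniform
#' @param name the table name (level-4 node under `/data/static`)
#' @return a \linkS4class{StaticTable}
#' @export
readStatic <- function(ix, population, name) {
  stopifnot(is(ix, "NSDFIndex"))
  row <- .index_row(ix, "static", population, name)
  file <- ix@path; dpath <- row$path
  a <- .h5attrs(file, dpath)
  srcs <- as.character(rhdf5::h5read(file, .source_scale_of(file, dpath)))
  units <- as.character(a$unit)
  if (.dtype_class(file, dpath) == "compound") {
    df <- rhdf5::h5read(file, dpath)
    df[] <- lapply(df, function(x) {
      if (is.factor(x)) x <- as.character(x)
      dim(x) <- NULL
      x
    })
    if (!length(units)) units <- rep("", ncol(df))
    return(StaticTable(population, name, srcs, df, units,
                       layout = "COMPOUND"))
  }
  mat <- .read_matrix(file, dpath)
  lsc <- .scales_by_class(file, dpath, 1L)$string
  labels <- if (length(lsc)) as.character(rhdf5::h5read(file, lsc[[1L]]))
            else paste0("V", seq_len(ncol(mat)))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  colnames(df) <- labels
  StaticTable(population, name, srcs, df,
              units = if (length(units)) units[1L] else "",
              layout = "HOMOGENEOUS_2D")
}

#' Find all data recorded from one source
#'
#' Returns the paths of every dataset under `/data` associated with the
#' given uid, through its source scale, its `source` attribute (ONED level
#' 5) or its map table.  With `useModelMap = TRUE` the model tree's `map`
#' attributes are used to restrict the search to the referenced mapping
#' tables; sources absent from the model tree fall back to the exhaustive
#' scan.  Unknown uids yield an empty vector.
#'
#' @inheritParams readUniform
#' @param uid source unique identifier
#' @param useModelMap consult `/model/modeltree` `map` attributes first?
#' @return character vector of dataset paths (sorted)
#' @export
sourcesToData <- function(ix, uid, useModelMap = TRUE) {
  stopifnot(is(ix, "NSDFIndex"), is.character(uid), length(uid) == 1L)
  file <- ix@path
  if (useModelMap && "modeltree" %in% ix@modelKinds) {
    refs <- .map_refs_of_uid(file, uid)
    if (!is.null(refs))
      return(sort(unique(unlist(
        lapply(refs, .datasets_of_map, ix = ix, uid = uid)))))
  }
  out <- character()
  d <- ix@datasets
  for (i in seq_len(nrow(d))) {
    if (d$variant[i] == "ONED") {
      map <- .read_map_table(file, .oned_table(file, d$category[i],
                                               d$population[i],
                                               d$variable[i]))
      out <- c(out, map$data[map$source == uid])
    } else {
      sc <- tryCatch(.source_scale_of(file, d$path[i]),
                     error = function(e) NULL)
      if (!is.null(sc) &&
          uid %in% as.character(rhdf5::h5read(file, sc)))
        out <- c(out, d$path[i])
    }
  }
  sort(unique(out))
}

# `map` attribute of the modeltree node carrying `uid`; NULL if the node is
# absent or carries no map references
.map_refs_of_uid <- function(file, uid) {
  found <- NULL
  rec <- function(g) {
    for (ch in .h5children(file, g)) {
      p <- paste0(g, "/", ch)
      if (!identical(.h5kind(file, p), "group")) next
      a <- .h5attrs(file, p)
      if (identical(as.character(.attr1(a, "uid", "")), uid)) {
        found <<- as.character(a$map)
        return()
      }
      rec(p)
    }
  }
  rec("/model/modeltree")
  if (is.null(found) || !length(found)) NULL else found
}

# datasets reachable from one mapping reference that contain `uid`
.datasets_of_map <- function(ref, ix, uid) {
  file <- ix@path
  kind <- .h5kind(file, ref)
  d <- ix@datasets
  if (identical(kind, "dataset") &&
      .dtype_class(file, ref) == "compound") {     # ONED map table
    map <- .read_map_table(file, ref)
    return(map$data[map$source == uid])
  }
  if (identical(kind, "dataset")) {                # source dimension scale
    if (!uid %in% as.character(rhdf5::h5read(file, ref)))
      return(character())
    parts <- strsplit(ref, "/", fixed = TRUE)[[1L]]  # /map/<cat>/<pop>
    hit <- d$category == parts[3L] & d$population == parts[4L]
    return(d$path[hit])
  }
  if (identical(kind, "group")) {                  # group of map tables
    return(unlist(lapply(.h5children(file, ref), function(ch)
      .datasets_of_map(paste0(ref, "/", ch), ix, uid))))
  }
  character()
}

#' Read the fallback model tree
#'
#' Reconstructs the hierarchy under `/model/modeltree` as
#' \linkS4class{ModelNode} objects.  The returned node is a virtual root
#' named `modeltree` whose children are the stored root components.
#'
#' @inheritParams readUniform
#' @return a \linkS4class{ModelNode}
#' @export
readModelTree <- function(ix) {
  stopifnot(is(ix, "NSDFIndex"))
  file <- ix@path
  known <- c("uid", "ontology", "map")
  rec <- function(path, name) {
    a <- .h5attrs(file, path)
    extras <- a[setdiff(names(a), known)]
    extras <- vapply(extras, function(x) as.character(x)[1L], character(1L))
    kids <- list()
    for (ch in .h5children(file, path)) {
      p <- paste0(path, "/", ch)
      if (identical(.h5kind(file, p), "group"))
        kids[[length(kids) + 1L]] <- rec(p, ch)
    }
    ModelNode(name, uid = as.character(.attr1(a, "uid", path)),
              ontology = as.character(a$ontology),
              attributes = extras, children = kids,
              mapRefs = as.character(a$map))
  }
  rec("/model/modeltree", "modeltree")
}

#' Read the file-level metadata
#'
#' @inheritParams readUniform
#' @return an \linkS4class{NSDFMetadata}
#' @export
readMetadata <- function(ix) {
  stopifnot(is(ix, "NSDFIndex"))
  a <- .h5attrs(ix@path, "/")
  args <- list()
  for (nm in .root_attr_names)
    if (!is.null(a[[nm]])) args[[nm]] <- as.character(a[[nm]])
  if (is.null(args$nsdf_version)) args$nsdf_version <- "unspecified"
  do.call(NSDFMetadata, args)
}
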