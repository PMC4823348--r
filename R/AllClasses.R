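# S4 containers mirroring the four NSDF data categories plus the model tree,
# file-level metadata and the handles used by the writer, reader and
# validator.

.categories <- c("static", "uniform", "nonuniform", "event")
.variants <- c("NUREGULAR", "ONED", "VLEN", "NANPADDED")

.strictly_increasing <- function(x) length(x) < 2L || all(diff(x) > 0)
.nondecreasing <- function(x) length(x) < 2L || all(diff(x) >= 0)

# ISO 8601 date-time, e.g. "2014-06-01T12:00:00Z" or with numeric offset;
# a bare date is also accepted.
.is_iso8601 <- function(x) {
  re <- paste0(
    "^\\d{4}-\\d{2}-\\d{2}",
    "([Tt ]\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?",
    "(Z|z|[+-]\\d{2}:?\\d{2})?)?$"
  )
  ok <- grepl(re, x)
  date <- substr(x, 1L, 10L)
  ok & !is.na(as.Date(date, format = "%Y-%m-%d"))
}

#' File-level NSDF metadata
#'
#' Root-group attributes of an NSDF file describing provenance: who created
#' the file, when, with which simulator and numerical method.  Timestamps
#' (`created`, `tstart`, `tend`) are ISO 8601 date-time strings;
#' `software` and `method` may hold several entries; `nsdf_version` must be
#' nonempty.
#'
#' @slot title,description,creator,contributor,license,rights free-text
#'   descriptors (`contributor`, `software`, `method` may be vectors)
#' @slot created,tstart,tend ISO 8601 timestamps; `created` is the file
#'   creation time, `tstart`/`tend` the wall-clock start/end of the run
#' @slot software,method simulator name(s) and numerical method(s)
#' @slot nsdf_version format version string
#' @export
setClass("NSDFMetadata", representation(
  title = "character", description = "character", creator = "character",
  contributor = "character", created = "character", license = "character",
  rights = "character", tstart = "character", tend = "character",
  software = "character", method = "character", nsdf_version = "character"
), validity = function(object) {
  for (f in c("created", "tstart", "tend")) {
    v <- slot(object, f)
    if (length(v) && any(nzchar(v)) && !all(.is_iso8601(v[nzchar(v)])))
      return(sprintf("'%s' is not an ISO 8601 date-time string", f))
  }
  if (!length(object@nsdf_version) || !nzchar(object@nsdf_version[1L]))
    return("nsdf_version must be a nonempty string")
  TRUE
})

#' Uniformly sampled time-series block
#'
#' A variable sampled from P sources at Q shared, regularly spaced time
#' points, held as a P x Q double matrix.  The time axis is described either
#' by `tstart`/`dt` (the j-th 0-based column samples time
#' `tstart + j * dt`) or by an explicit vector of Q sampling times.
#'
#' @slot population,variable level-3 population and level-4 variable name
#' @slot sources unique identifiers of the P data sources (matrix rows)
#' @slot values P x Q numeric matrix
#' @slot unit physical unit of the values; \code{field} the recorded field
#'   name; \code{tunit} the unit of the time axis
#' @slot tstart,dt start time and sampling interval (`dt > 0`), in `tunit`
#' @slot explicitTimes optional explicit time axis of length Q
#' @export
setClass("UniformBlock", representation(
  population = "character", variable = "character", sources = "character",
  values = "matrix", unit = "character", field = "character",
  tstart = "numeric", dt = "numeric", tunit = "character",
  explicitTimes = "numeric"
), validity = function(object) {
  if (nrow(object@values) != length(object@sources))
    return("number of rows of 'values' must equal the number of sources")
  if (!is.numeric(object@values))
    return("'values' must be numeric")
  if (length(object@explicitTimes)) {
    if (length(object@explicitTimes) != ncol(object@values))
      return("length of 'explicitTimes' must equal the number of columns")
    if (!.strictly_increasing(object@explicitTimes))
      return("'explicitTimes' must be strictly increasing")
  } else if (ncol(object@values) > 0L) {
    if (is.na(object@dt) || object@dt <= 0)
      return("'dt' must be positive when no explicit time axis is given")
  }
  TRUE
})

#' Nonuniformly sampled ragged series
#'
#' Per-source value arrays of (possibly) unequal length with per-source
#' sampling-time arrays, or one shared time axis when all sources were
#' sampled at the same (irregular) instants.  A set `sharedTimes` is what
#' makes the series eligible for the NUREGULAR storage variant.
#'
#' @slot population,variable,unit,field,tunit as in
#'   \linkS4class{UniformBlock}
#' @slot sources unique identifiers of the data sources
#' @slot values list of numeric vectors, one per source
#' @slot times list of strictly increasing numeric vectors congruent with
#'   `values`; empty when `sharedTimes` is used
#' @slot sharedTimes optional shared sampling-time axis
#' @export
setClass("RaggedSeries", representation(
  population = "character", variable = "character", sources = "character",
  values = "list", times = "list", sharedTimes = "numeric",
  unit = "character", field = "character", tunit = "character"
), validity = function(object) {
  n <- length(object@sources)
  if (length(object@values) != n)
    return("'values' must have one entry per source")
  if (length(object@sharedTimes)) {
    m <- length(object@sharedTimes)
    if (!all(lengths(object@values) == m))
      return("all value vectors must match the shared time axis length")
    if (!.strictly_increasing(object@sharedTimes))
      return("'sharedTimes' must be strictly increasing")
  } else {
    if (length(object@times) != n)
      return("'times' must have one entry per source")
    if (!all(lengths(object@times) == lengths(object@values)))
      return("per-source 'times' and 'values' must have equal lengths")
    if (!all(vapply(object@times, .strictly_increasing, logical(1L))))
      return("each per-source time vector must be strictly increasing")
  }
  TRUE
})

#' Set of event (spike) time arrays
#'
#' Discrete occurrence times, one sorted array per source; the number of
#' events may differ between sources, and a source with no events is held
#' as an empty vector.
#'
#' @slot population,variable,unit,field as in \linkS4class{UniformBlock}
#' @slot sources unique identifiers of the event sources
#' @slot times list of nondecreasing numeric vectors, one per source
#' @export
setClass("EventSet", representation(
  population = "character", variable = "character", sources = "character",
  times = "list", unit = "character", field = "character"
), validity = function(object) {
  if (length(object@times) != length(object@sources))
    return("'times' must have one entry per source")
  if (!all(vapply(object@times, .nondecreasing, logical(1L))))
    return("each event-time vector must be sorted nondecreasing")
  TRUE
})

#' Static (non-time-varying) table
#'
#' Data that do not change over the simulation: morphology coordinates,
#' biophysical parameters, connectivity.  Either a homogeneous numeric 2D
#' layout (one shared unit, labelled columns) or a compound record layout
#' with named, individually united fields; fields that carry no physical
#' unit (e.g. indices or identifiers) take the empty string as unit.
#'
#' @slot population level-3 population name; \code{name} the table name
#' @slot sources row identifiers (one per table row)
#' @slot layout `"HOMOGENEOUS_2D"` or `"COMPOUND"`
#' @slot data data.frame of the table (all-numeric for HOMOGENEOUS_2D)
#' @slot units length-1 shared unit (HOMOGENEOUS_2D) or one unit per field
#'   (COMPOUND, empty strings allowed)
#' @export
setClass("StaticTable", representation(
  population = "character", name = "character", sources = "character",
  layout = "character", data = "data.frame", units = "character"
), validity = function(object) {
  if (!object@layout %in% c("HOMOGENEOUS_2D", "COMPOUND"))
    return("layout must be HOMOGENEOUS_2D or COMPOUND")
  if (nrow(object@data) != length(object@sources))
    return("row count must equal the number of sources")
  if (object@layout == "HOMOGENEOUS_2D") {
    if (!all(vapply(object@data, is.numeric, logical(1L))))
      return("HOMOGENEOUS_2D tables must be all-numeric")
    if (length(object@units) != 1L)
      return("HOMOGENEOUS_2D tables take a single shared unit")
  } else if (length(object@units) != ncol(object@data)) {
    return("COMPOUND tables need one unit entry per field")
  }
  TRUE
})

#' Node of the fallback hierarchical model description
#'
#' One component of the model tree stored under `/model/modeltree`: a named
#' group carrying a unique identifier, an optional ontology term, free-form
#' string attributes, child components and, for components with recorded
#' data, paths of the mapping tables under `/map` (`mapRefs`).
#'
#' @slot name component name (no path separator)
#' @slot uid unique identifier within the file's model tree
#' @slot ontology optional ontology term (length 0 or 1)
#' @slot attributes named character vector of extra attributes
#' @slot children list of child \code{ModelNode}s
#' @slot mapRefs character vector of mapping-dataset paths
#' @export
setClass("ModelNode", representation(
  name = "character", uid = "character", ontology = "character",
  attributes = "character", children = "list", mapRefs = "character"
), validity = function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a nonempty string")
  if (grepl("/", object@name, fixed = TRUE))
    return("'name' must not contain the path separator '/'")
  if (length(object@uid) != 1L || !nzchar(object@uid))
    return("'uid' must be a nonempty string")
  if (length(object@ontology) > 1L)
    return("'ontology' must have length 0 or 1")
  if (!all(vapply(object@children, is, logical(1L), "ModelNode")))
    return("all children must be ModelNode objects")
  TRUE
})

#' Writer handle for an NSDF file
#'
#' Returned by [createNSDF()].  Carries the target path and the compression
#' dialect; every writing operation opens and closes the file, so handles
#' remain valid across calls and sessions.
#'
#' @slot path file path
#' @slot compression `"none"` or `"gzip"`
#' @slot level gzip level (used when compression is `"gzip"`)
#' @slot mode `"create"` or `"append"`
#' @export
setClass("NSDFFile", representation(
  path = "character", compression = "character", level = "integer",
  mode = "character"
))

#' Index of an opened NSDF file
#'
#' Returned by [openNSDF()]: an inventory of every population and variable
#' under `/data` with the detected storage variant, the model-description
#' kinds present, and any layout problems encountered while indexing.
#'
#' @slot path file path
#' @slot datasets data.frame with columns category, population, variable,
#'   variant and path
#' @slot modelKinds subset of modeltree, filecontents, filerefs, links
#' @slot issues character vector of unrecognisable-layout reports
#' @export
setClass("NSDFIndex", representation(
  path = "character", datasets = "data.frame", modelKinds = "character",
  issues = "character"
))

#' Conformance report
#'
#' Result of [validateNSDF()]: a table of findings (severity, stable rule
#' id, node path, message).  A file conforms when it has no error-severity
#' findings.
#'
#' @slot path validated file
#' @slot findings data.frame with columns severity, rule, node, message
#' @slot strict whether strict mode was used
#' @export
setClass("NSDFValidation", representation(
  path = "character", findings = "data.frame", strict = "logical"
))

#' Bundle of generated fixture containers
#'
#' Output of the fixture generators ([genTwoNeurons()], [genHH()],
#' [genBenchmark()]): in-memory containers for every category plus a
#' model tree and a manifest of expected counts used by self-checks.
#'
#' @slot modelTree a \linkS4class{ModelNode} or NULL
#' @slot static,uniform,nonuniform,events lists of containers
#' @slot manifest named list of expected counts
#' @export
setClass("FixtureBundle", representation(
  modelTree = "ANY", static = "list", uniform = "list",
  nonuniform = "list", events = "list", manifest = "list"
), validity = function(object) {
  if (!is.null(object@modelTree) && !is(object@modelTree, "ModelNode"))
    return("modelTree must be a ModelNode or NULL")
  TRUE
})
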