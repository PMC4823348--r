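#' @include AllClasses.R
NULL

#' Accessors for NSDF containers
#'
#' Small family of getters shared by the in-memory containers:
#' \code{population()} and \code{varName()} return the level-3 population
#' name and the level-4 variable name, \code{sources()} the unique
#' identifiers of the recorded model components, \code{values()} the payload
#' (a matrix for uniform blocks, a list of numeric vectors for ragged
#' series), \code{times()} the sampling-time axis (computed from
#' \code{tstart}/\code{dt} for uniform data when no explicit axis is
#' stored), \code{unitString()} the physical unit, and \code{manifest()} the
#' expected-counts manifest of a fixture bundle.
#'
#' @param x a container object
#' @return see Details; \code{sources()} a character vector, \code{values()}
#'   a matrix or list, \code{times()} a numeric vector or list thereof.
#' @name nsdf-accessors
#' @aliases population varName sources values times unitString manifest
NULL

#' @rdname nsdf-accessors
#' @export
setGeneric("population", function(x) standardGeneric("population"))

#' @rdname nsdf-accessors
#' @export
setGeneric("varName", function(x) standardGeneric("varName"))

#' @rdname nsdf-accessors
#' @export
setGeneric("sources", function(x) standardGeneric("sources"))

#' @rdname nsdf-accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname nsdf-accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))

#' @rdname nsdf-accessors
#' @export
setGeneric("unitString", function(x) standardGeneric("unitString"))

#' @rdname nsdf-accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname validateNSDF
#' @export
setGeneric("conforms", function(x) standardGeneric("conforms"))

#' @rdname validateNSDF
#' @export
setGeneric("findings", function(x) standardGeneric("findings"))
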