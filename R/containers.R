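# Constructors, accessors and show() methods for the data containers.

#' @rdname NSDFMetadata-class
#' @param title,description,creator,contributor,created,license,rights,tstart,tend,software,method,nsdf_version
#'   see the class slots; `created` defaults to the current UTC time
#' @return an \linkS4class{NSDFMetadata} object
#' @examples
#' NSDFMetadata(title = "two-neuron demo", creator = "jdoe")
#' @export
NSDFMetadata <- function(title = "untitled", description = character(),
                         creator = unname(Sys.info()["user"]),
                         contributor = character(),
                         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                          tz = "UTC"),
                         license = character(), rights = character(),
                         tstart = character(), tend = character(),
                         software = "nsdf R package",
                         method = "unspecified",
                         nsdf_version = "1.0") {
  new("NSDFMetadata", title = as.character(title),
      description = as.character(description),
      creator = as.character(creator),
      contributor = as.character(contributor),
      created = as.character(created), license = as.character(license),
      rights = as.character(rights), tstart = as.character(tstart),
      tend = as.character(tend), software = as.character(software),
      method = as.character(method),
      nsdf_version = as.character(nsdf_version))
}

#' @rdname UniformBlock-class
#' @param population,variable,sources,values,unit,field,tstart,dt,tunit,explicitTimes
#'   see the class slots; `field` defaults to `variable`
#' @return a \linkS4class{UniformBlock}
#' @examples
#' UniformBlock("neuronA", "Vm", sources = c("/m/a/soma", "/m/a/axon"),
#'              values = matrix(rnorm(10), 2), unit = "mV",
#'              tstart = 0, dt = 1e-4)
#' @export
UniformBlock <- function(population, variable, sources, values, unit,
                         field = variable, tstart = 0, dt = NA_real_,
                         tunit = "s", explicitTimes = numeric()) {
  if (!is.matrix(values)) values <- matrix(as.numeric(values), nrow = length(sources))
  storage.mode(values) <- "double"
  new("UniformBlock", population = population, variable = variable,
      sources = as.character(sources), values = values, unit = unit,
      field = field, tstart = as.numeric(tstart), dt = as.numeric(dt),
      tunit = tunit, explicitTimes = as.numeric(explicitTimes))
}

#' @rdname RaggedSeries-class
#' @param population,variable,sources,values,times,sharedTimes,unit,field,tunit
#'   see the class slots
#' @return a \linkS4class{RaggedSeries}
#' @export
RaggedSeries <- function(population, variable, sources, values,
                         times = list(), sharedTimes = numeric(), unit,
                         field = variable, tunit = "s") {
  new("RaggedSeries", population = population, variable = variable,
      sources = as.character(sources),
      values = lapply(values, as.numeric), times = lapply(times, as.numeric),
      sharedTimes = as.numeric(sharedTimes), unit = unit, field = field,
      tunit = tunit)
}

#' @rdname EventSet-class
#' @param population,variable,sources,times,unit,field see the class slots
#' @return an \linkS4class{EventSet}
#' @export
EventSet <- function(population, variable, sources, times, unit = "s",
                     field = variable) {
  new("EventSet", population = population, variable = variable,
      sources = as.character(sources), times = lapply(times, as.numeric),
      unit = unit, field = field)
}

#' @rdname StaticTable-class
#' @param population,name,sources,data,units,layout see the class slots;
#'   the layout defaults to COMPOUND unless every column is numeric and a
#'   single unit is given
#' @return a \linkS4class{StaticTable}
#' @export
StaticTable <- function(population, name, sources, data, units,
                        layout = if (all(vapply(data, is.numeric, logical(1L))) &&
                                     length(units) == 1L)
                          "HOMOGENEOUS_2D" else "COMPOUND") {
  new("StaticTable", population = population, name = name,
      sources = as.character(sources), layout = layout,
      data = as.data.frame(data, stringsAsFactors = FALSE),
      units = as.character(units))
}

#' @rdname ModelNode-class
#' @param name,uid,ontology,attributes,children,mapRefs see the class slots;
#'   `uid` defaults to the node name turned into an absolute path
#' @return a \linkS4class{ModelNode}
#' @export
ModelNode <- function(name, uid = makeUid(name), ontology = character(),
                      attributes = character(), children = list(),
                      mapRefs = character()) {
  new("ModelNode", name = name, uid = uid,
      ontology = as.character(ontology),
      attributes = if (length(attributes)) attributes else
        stats::setNames(character(), character()),
      children = children, mapRefs = as.character(mapRefs))
}

## accessors ----------------------------------------------------------------

#' @rdname nsdf-accessors
setMethod("population", "UniformBlock", function(x) x@population)
#' @rdname nsdf-accessors
setMethod("population", "RaggedSeries", function(x) x@population)
#' @rdname nsdf-accessors
setMethod("population", "EventSet", function(x) x@population)
#' @rdname nsdf-accessors
setMethod("population", "StaticTable", function(x) x@population)

#' @rdname nsdf-accessors
setMethod("varName", "UniformBlock", function(x) x@variable)
#' @rdname nsdf-accessors
setMethod("varName", "RaggedSeries", function(x) x@variable)
#' @rdname nsdf-accessors
setMethod("varName", "EventSet", function(x) x@variable)
#' @rdname nsdf-accessors
setMethod("varName", "StaticTable", function(x) x@name)

#' @rdname nsdf-accessors
setMethod("sources", "UniformBlock", function(x) x@sources)
#' @rdname nsdf-accessors
setMethod("sources", "RaggedSeries", function(x) x@sources)
#' @rdname nsdf-accessors
setMethod("sources", "EventSet", function(x) x@sources)
#' @rdname nsdf-accessors
setMethod("sources", "StaticTable", function(x) x@sources)

#' @rdname nsdf-accessors
setMethod("values", "UniformBlock", function(x) x@values)
#' @rdname nsdf-accessors
setMethod("values", "RaggedSeries", function(x) x@values)
#' @rdname nsdf-accessors
setMethod("values", "StaticTable", function(x) x@data)

#' @rdname nsdf-accessors
setMethod("times", "UniformBlock", function(x) {
  if (length(x@explicitTimes)) x@explicitTimes
  else if (ncol(x@values) == 0L) numeric()
  else uniformTimeAxis(x@tstart, x@dt, ncol(x@values))
})
#' @rdname nsdf-accessors
setMethod("times", "RaggedSeries", function(x) {
  if (length(x@sharedTimes)) rep(list(x@sharedTimes), length(x@sources))
  else x@times
})
#' @rdname nsdf-accessors
setMethod("times", "EventSet", function(x) x@times)

#' @rdname nsdf-accessors
setMethod("unitString", "UniformBlock", function(x) x@unit)
#' @rdname nsdf-accessors
setMethod("unitString", "RaggedSeries", function(x) x@unit)
#' @rdname nsdf-accessors
setMethod("unitString", "EventSet", function(x) x@unit)
#' @rdname nsdf-accessors
setMethod("unitString", "StaticTable", function(x) x@units)

#' @rdname nsdf-accessors
setMethod("manifest", "FixtureBundle", function(x) x@manifest)

## show ---------------------------------------------------------------------

setMethod("show", "UniformBlock", function(object) {
  cat(sprintf("UniformBlock '%s/%s': %d source(s) x %d sample(s) [%s]\n",
              object@population, object@variable, nrow(object@values),
              ncol(object@values), object@unit))
  if (length(object@explicitTimes))
    cat("  explicit time axis\n")
  else
    cat(sprintf("  tstart=%g dt=%g %s\n", object@tstart, object@dt,
                object@tunit))
})

setMethod("show", "RaggedSeries", function(object) {
  cat(sprintf("RaggedSeries '%s/%s': %d source(s), lengths [%s] [%s]\n",
              object@population, object@variable, length(object@sources),
              paste(lengths(object@values), collapse = ", "), object@unit))
  if (length(object@sharedTimes))
    cat(sprintf("  shared time axis of length %d\n",
                length(object@sharedTimes)))
})

setMethod("show", "EventSet", function(object) {
  cat(sprintf("EventSet '%s/%s': %d source(s), event counts [%s]\n",
              object@population, object@variable, length(object@sources),
              paste(lengths(object@times), collapse = ", ")))
})

setMethod("show", "StaticTable", function(object) {
  cat(sprintf("StaticTable '%s/%s' (%s): %d row(s), fields: %s\n",
              object@population, object@name, object@layout,
              nrow(object@data),
              paste(colnames(object@data), collapse = ", ")))
})

setMethod("show", "ModelNode", function(object) {
  rec <- function(n, depth) {
    cat(strrep("  ", depth), n@name, "  [", n@uid, "]\n", sep = "")
    for (ch in n@children) rec(ch, depth + 1L)
  }
  rec(object, 0L)
})

setMethod("show", "NSDFFile", function(object) {
  cat(sprintf("NSDFFile: %s (mode=%s, compression=%s)\n", object@path,
              object@mode, object@compression))
})

setMethod("show", "NSDFIndex", function(object) {
  cat("NSDFIndex:", object@path, "\n")
  d <- object@datasets
  if (!nrow(d)) {
    cat("  (no datasets)\n")
  } else {
    for (cat_ in unique(d$category)) {
      cat(" ", cat_, "\n")
      dd <- d[d$category == cat_, , drop = FALSE]
      for (i in seq_len(nrow(dd)))
        cat(sprintf("    %s/%s%s\n", dd$population[i], dd$variable[i],
                    if (nzchar(dd$variant[i]))
                      paste0(" [", dd$variant[i], "]") else ""))
    }
  }
  if (length(object@modelKinds))
    cat("  model:", paste(object@modelKinds, collapse = ", "), "\n")
  if (length(object@issues))
    cat("  issues:", length(object@issues), "\n")
})

setMethod("show", "NSDFValidation", function(object) {
  f <- object@findings
  cat(sprintf("NSDF validation of '%s': %s (%d error(s), %d warning(s), %d info)\n",
              object@path,
              if (conforms(object)) "CONFORMS" else "DOES NOT CONFORM",
              sum(f$severity == "error"), sum(f$severity == "warning"),
              sum(f$severity == "info")))
  if (nrow(f))
    for (i in seq_len(nrow(f)))
      cat(sprintf("  [%s] %s %s: %s\n", f$severity[i], f$rule[i],
                  f$node[i], f$message[i]))
})

setMethod("show", "FixtureBundle", function(object) {
  cat(sprintf(paste0("FixtureBundle: %d static, %d uniform, %d nonuniform, ",
                     "%d event container(s)\n"),
              length(object@static), length(object@uniform),
              length(object@nonuniform), length(object@events)))
})

#' @rdname validateNSDF
setMethod("conforms", "NSDFValidation", function(x)
  !any(x@findings$severity == "error"))

#' @rdname validateNSDF
setMethod("findings", "NSDFValidation", function(x) x@findings)
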