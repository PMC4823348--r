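# Seeded fixture generators: the two-neuron worked example, the
# single-compartment Hodgkin-Huxley recording, the benchmark corpus, a
# writer for whole bundles and a corruption tool for validator testing.

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# smooth-ish pseudo time series: integrated noise around a baseline
.smooth_series <- function(n, baseline = 0, scale = 1) {
  if (!n) return(numeric())
  baseline + scale * cumsum(stats::rnorm(n)) / sqrt(n)
}

#' Two-neuron worked-example fixture
#'
#' Generates the canonical two-neuron scenario: neuronA and neuronB, each
#' with dend, soma and axon compartments, connected by exactly two static
#' synapses; membrane potential and transmembrane current recorded
#' uniformly from neuronA's soma and axon; transmembrane current of
#' neuronB's dend and soma recorded at `M` shared nonuniform time points;
#' and spike trains with exactly 11 events for neuronA and 13 for neuronB.
#' All values are pseudo-random functions of `seed`; shapes and counts are
#' fixed.
#'
#' @param seed integer seed
#' @param M number of shared nonuniform sampling points
#' @param Q number of uniform samples
#' @param dt uniform sampling interval in seconds
#' @return a \linkS4class{FixtureBundle}
#' @examples
#' b <- genTwoNeurons(seed = 0)
#' manifest(b)
#' @export
genTwoNeurons <- function(seed = 0, M = 47L, Q = 100L, dt = 1e-4) {
  .withSeed(seed, {
    comp <- function(neuron, part)
      makeUid(c("model", "modeltree", neuron, part))
    neuron <- function(name) ModelNode(
      name, uid = makeUid(c("model", "modeltree", name)),
      children = lapply(c("dend", "soma", "axon"), function(p)
        ModelNode(p, uid = comp(name, p))))
    tree <- ModelNode("network", uid = "/model/modeltree",
                      children = list(neuron("neuronA"),
                                      neuron("neuronB")))

    uA <- c(comp("neuronA", "soma"), comp("neuronA", "axon"))
    vm <- UniformBlock("neuronA", "Vm", uA,
                       values = rbind(.smooth_series(Q, -65, 5),
                                      .smooth_series(Q, -65, 5)),
                       unit = "mV", tstart = 0, dt = dt, tunit = "s")
    im <- UniformBlock("neuronA", "Im", uA,
                       values = rbind(.smooth_series(Q, 0, 0.1),
                                      .smooth_series(Q, 0, 0.1)),
                       unit = "nA", tstart = 0, dt = dt, tunit = "s")

    uB <- c(comp("neuronB", "dend"), comp("neuronB", "soma"))
    nu_t <- sort(stats::runif(M, 0, 10))
    nu <- RaggedSeries("neuronB", "Im", uB,
                       values = list(.smooth_series(M, 0, 0.1),
                                     .smooth_series(M, 0, 0.1)),
                       sharedTimes = nu_t, unit = "nA", tunit = "s")

    ev <- EventSet("neurons", "spike",
                   sources = c(makeUid(c("model", "modeltree", "neuronA")),
                               makeUid(c("model", "modeltree", "neuronB"))),
                   times = list(sort(stats::runif(11, 0, 10)),
                                sort(stats::runif(13, 0, 10))),
                   unit = "s")

    syn <- StaticTable(
      "synapses", "connections", sources = c("syn00", "syn01"),
      data = data.frame(
        pre = c(comp("neuronA", "axon"), comp("neuronB", "axon")),
        post = c(comp("neuronB", "dend"), comp("neuronA", "dend")),
        weight = stats::runif(2, 0.1, 1),
        stringsAsFactors = FALSE),
      units = c("", "", "nS"), layout = "COMPOUND")

    bundle <- new("FixtureBundle", modelTree = tree, static = list(syn),
                  uniform = list(vm, im), nonuniform = list(nu),
                  events = list(ev),
                  manifest = list(synapses = 2L, eventsA = 11L,
                                  eventsB = 13L, uniformQ = as.integer(Q),
                                  nonuniformM = as.integer(M)))
    .check_manifest(bundle)
    bundle
  })
}

#' Single-compartment Hodgkin-Huxley fixture
#'
#' One compartment with Na and K channel child entities: a uniform
#' membrane-potential series from the compartment, a two-row `IChannel`
#' dataset holding the Na and K channel currents, and a total membrane
#' current series.
#'
#' @param seed integer seed
#' @param Q number of uniform samples
#' @param dt sampling interval in seconds
#' @return a \linkS4class{FixtureBundle}
#' @export
genHH <- function(seed = 0, Q = 200L, dt = 25e-6) {
  .withSeed(seed, {
    uidc <- makeUid(c("model", "modeltree", "compartment"))
    uids <- c(Na = makeUid(c("model", "modeltree", "compartment", "Na")),
              K = makeUid(c("model", "modeltree", "compartment", "K")))
    tree <- ModelNode("compartment", uid = uidc, children = list(
      ModelNode("Na", uid = unname(uids["Na"])),
      ModelNode("K", uid = unname(uids["K"]))))
    vm <- UniformBlock("compartment", "Vm", uidc,
                       values = matrix(.smooth_series(Q, -65, 10),
                                       nrow = 1L),
                       unit = "mV", tstart = 0, dt = dt, tunit = "s")
    ich <- UniformBlock("channels", "IChannel", unname(uids),
                        values = rbind(.smooth_series(Q, 0, 0.5),
                                       .smooth_series(Q, 0, 0.5)),
                        unit = "nA", tstart = 0, dt = dt, tunit = "s")
    im <- UniformBlock("compartment", "Im", uidc,
                       values = matrix(.smooth_series(Q, 0, 0.5),
                                       nrow = 1L),
                       unit = "nA", tstart = 0, dt = dt, tunit = "s")
    bundle <- new("FixtureBundle", modelTree = tree, static = list(),
                  uniform = list(vm, ich, im), nonuniform = list(),
                  events = list(),
                  manifest = list(vmSources = 1L, ichannelRows = 2L,
                                  uniformQ = as.integer(Q)))
    .check_manifest(bundle)
    bundle
  })
}

#' Benchmark corpus generator
#'
#' Random data with the benchmark-protocol shapes: at scale 1, 100 uniform
#' datasets of 100 sources x 10000 samples, and for nonuniform and event
#' data per-source row lengths drawn uniformly between 5000 and 10000.
#' `scaleFactor` shrinks all counts and lengths proportionally (floored,
#' minimum 1); a fixed seed makes the data identical across runs.
#'
#' @param seed integer seed
#' @param scaleFactor proportional shrink factor in (0, 1]
#' @param categories subset of uniform/nonuniform/event to generate
#' @return a \linkS4class{FixtureBundle}
#' @export
genBenchmark <- function(seed = 0, scaleFactor = 1,
                         categories = c("uniform", "nonuniform",
                                        "event")) {
  if (!is.numeric(scaleFactor) || scaleFactor <= 0 || scaleFactor > 1)
    stop("'scaleFactor' must be in (0, 1]")
  categories <- match.arg(categories,
                          c("uniform", "nonuniform", "event"),
                          several.ok = TRUE)
  s <- scaleFactor
  nDatasets <- max(1L, as.integer(floor(100 * s)))
  P <- max(1L, as.integer(floor(100 * s)))
  Q <- max(1L, as.integer(floor(10000 * s)))
  lo <- max(1L, as.integer(floor(5000 * s)))
  hi <- max(lo, as.integer(floor(10000 * s)))
  draw_lens <- function(P)
    if (lo == hi) rep(lo, P) else
      lo + sample.int(hi - lo + 1L, P, replace = TRUE) - 1L
  ## one RNG substream per category, so the data generated for a category
  ## do not depend on which other categories were requested
  uniform <- list(); nonuniform <- list(); events <- list()
  if ("uniform" %in% categories)
    uniform <- .withSeed(seed + 1L, lapply(seq_len(nDatasets), function(i) {
      pop <- sprintf("upop%03d", i)
      UniformBlock(pop, "Vm",
                   sources = sprintf("/bench/%s/c%03d", pop, seq_len(P)),
                   values = matrix(stats::runif(P * Q), nrow = P),
                   unit = "mV", tstart = 0, dt = 1e-4, tunit = "s")
    }))
  if ("nonuniform" %in% categories)
    nonuniform <- .withSeed(seed + 2L,
                            lapply(seq_len(nDatasets), function(i) {
      pop <- sprintf("npop%03d", i)
      lens <- draw_lens(P)
      RaggedSeries(pop, "Im",
                   sources = sprintf("/bench/%s/c%03d", pop, seq_len(P)),
                   values = lapply(lens, stats::runif),
                   times = lapply(lens, function(k)
                     sort(stats::runif(k, 0, 10))),
                   unit = "nA", tunit = "s")
    }))
  if ("event" %in% categories)
    events <- .withSeed(seed + 3L, lapply(seq_len(nDatasets), function(i) {
      pop <- sprintf("epop%03d", i)
      lens <- draw_lens(P)
      EventSet(pop, "spike",
               sources = sprintf("/bench/%s/c%03d", pop, seq_len(P)),
               times = lapply(lens, function(k)
                 sort(stats::runif(k, 0, 10))),
               unit = "s")
    }))
  new("FixtureBundle", modelTree = NULL, static = list(),
      uniform = uniform, nonuniform = nonuniform, events = events,
      manifest = list(nDatasets = nDatasets, P = P, Q = Q,
                      raggedRange = c(lo, hi)))
}

# fixture self-check: manifest counts must equal actual container sizes
.check_manifest <- function(bundle) {
  m <- bundle@manifest
  ok <- TRUE
  if (!is.null(m$synapses))
    ok <- ok && nrow(bundle@static[[1L]]@data) == m$synapses
  if (!is.null(m$eventsA))
    ok <- ok && length(bundle@events[[1L]]@times[[1L]]) == m$eventsA
  if (!is.null(m$eventsB))
    ok <- ok && length(bundle@events[[1L]]@times[[2L]]) == m$eventsB
  if (!is.null(m$uniformQ))
    ok <- ok && all(vapply(bundle@uniform, function(b)
      ncol(b@values) == m$uniformQ, logical(1L)))
  if (!is.null(m$nonuniformM))
    ok <- ok && length(bundle@nonuniform[[1L]]@sharedTimes) == m$nonuniformM
  if (!is.null(m$vmSources))
    ok <- ok && nrow(bundle@uniform[[1L]]@values) == m$vmSources
  if (!is.null(m$ichannelRows))
    ok <- ok && nrow(bundle@uniform[[2L]]@values) == m$ichannelRows
  if (!ok) stop("fixture manifest does not match the generated containers")
  invisible(bundle)
}

#' Write a fixture bundle to an NSDF file
#'
#' Materialises every container of a bundle through the writer, using one
#' consistent storage variant per ragged category, and stores the model
#' tree with `map` attributes pointing at the mapping datasets of the
#' populations each component was recorded in.
#'
#' @param bundle a \linkS4class{FixtureBundle}
#' @param path target file
#' @param eventVariant variant for event data (ONED/VLEN/NANPADDED)
#' @param nonuniformVariant variant for nonuniform data; the default picks
#'   NUREGULAR when the series carries a shared time axis, VLEN otherwise
#' @param compression,level,metadata,timeMode,extendible passed to the
#'   writer
#' @return the \linkS4class{NSDFFile} handle, invisibly
#' @export
writeBundle <- function(bundle, path, eventVariant = "VLEN",
                        nonuniformVariant = NULL, compression = "none",
                        level = 6L,
                        metadata = NSDFMetadata(title = "nsdf fixture"),
                        timeMode = "attrs", extendible = FALSE) {
  stopifnot(is(bundle, "FixtureBundle"))
  h <- createNSDF(path, metadata, compression = compression,
                  level = as.integer(level))
  for (tb in bundle@static) addStatic(h, tb)
  for (ub in bundle@uniform) addUniform(h, ub, timeMode = timeMode)
  for (rs in bundle@nonuniform) {
    v <- nonuniformVariant
    if (is.null(v))
      v <- if (length(rs@sharedTimes)) "NUREGULAR" else "VLEN"
    addNonuniform(h, rs, variant = v, extendible = extendible)
  }
  for (ev in bundle@events)
    addEvents(h, ev, variant = eventVariant, extendible = extendible)
  if (!is.null(bundle@modelTree)) {
    maps <- .collect_map_paths(h@path)
    tree <- .attach_map_refs(bundle@modelTree, maps)
    if (identical(tree@uid, "/model/modeltree")) {
      for (ch in tree@children) addModelTree(h, ch)
    } else {
      addModelTree(h, tree)
    }
  }
  invisible(h)
}

# mapping-dataset path(s) per source uid, derived from the file layout
.collect_map_paths <- function(file) {
  out <- list()
  push <- function(uid, p) out[[uid]] <<- unique(c(out[[uid]], p))
  for (cat in intersect(.h5children(file, "/map"), .categories)) {
    for (ch in .h5children(file, paste0("/map/", cat))) {
      p <- sprintf("/map/%s/%s", cat, ch)
      kind <- .h5kind(file, p)
      if (identical(kind, "dataset")) {
        if (.dtype_class(file, p) != "string") next
        for (uid in as.character(rhdf5::h5read(file, p))) push(uid, p)
      } else if (identical(kind, "group")) {
        for (tb in .h5children(file, p)) {
          tpath <- paste0(p, "/", tb)
          if (.dtype_class(file, tpath) == "compound")
            for (uid in .read_map_table(file, tpath)$source)
              push(uid, tpath)
        }
      }
    }
  }
  out
}

.attach_map_refs <- function(node, maps) {
  refs <- maps[[node@uid]]
  if (!is.null(refs)) node@mapRefs <- sort(unique(c(node@mapRefs, refs)))
  node@children <- lapply(node@children, .attach_map_refs, maps = maps)
  node
}

#' Corrupt a conforming NSDF file to trigger one validation rule
#'
#' Copies the file and applies the minimal targeted mutation that violates
#' the requested rule (R1-R12), for validator testing.  The input must
#' contain a suitable target for the rule (e.g. a NANPADDED event dataset
#' for R6); otherwise an error names what is missing.
#'
#' @param path a conforming NSDF file
#' @param rule rule id, `"R1"` to `"R12"`
#' @param out output path for the corrupted copy
#' @param seed unused randomness reserve (mutations are deterministic)
#' @return `out`, invisibly
#' @export
corruptNSDF <- function(path, rule,
                        out = tempfile(fileext = ".h5"), seed = 0) {
  rule <- match.arg(rule, .validator_rules)
  stopifnot(file.exists(path))
  file.copy(path, out, overwrite = TRUE)
  ix <- openNSDF(out)
  d <- ix@datasets
  pick <- function(cond, what) {
    i <- which(cond)
    if (!length(i)) stop("file has no target for rule ", rule, ": ", what)
    d[i[1L], ]
  }
  switch(rule,
    R1 = rhdf5::h5delete(out, "/map"),
    R2 = rhdf5::h5createGroup(out, "/data/bogus"),
    R3 = {
      row <- pick(d$variant != "ONED", "a non-ONED dataset")
      .h5delete_attr(out, row$path, "unit")
    },
    R4 = {
      row <- pick(d$category == "uniform", "a uniform dataset")
      orphan <- sprintf("/data/uniform/%s/orphan", row$population)
      .write_vector_dataset(out, orphan, c(0, 0))
      .h5write_attr(out, orphan, "unit", "mV")
      .h5write_attr(out, orphan, "field", "orphan")
      .h5write_attr(out, orphan, "tstart", 0)
      .h5write_attr(out, orphan, "dt", 1e-4)
    },
    R5 = {
      row <- pick(d$category == "uniform", "a uniform dataset")
      .h5delete_attr(out, row$path, "tstart")
      .h5delete_attr(out, row$path, "dt")
    },
    R6 = {
      row <- pick(d$variant == "NANPADDED", "a NANPADDED dataset")
      lens <- .nan_row_lengths(.read_matrix(out, row$path))
      i <- which(lens >= 2L)[1L]
      if (is.na(i)) stop("no row with >= 2 entries to corrupt")
      rhdf5::h5write(NaN, out, row$path, index = list(1L, i))
    },
    R7 = {
      row <- pick(d$variant == "ONED", "an ONED variable")
      tbl <- .oned_table(out, row$category, row$population, row$variable)
      map <- .read_map_table(out, tbl)
      map$data[1L] <- "/data/nonexistent"
      rhdf5::h5delete(out, tbl)
      rhdf5::h5write(map, out, tbl)
    },
    R8 = {
      row <- pick(d$category %in% c("event", "nonuniform") &
                  d$variant != "NANPADDED",
                  "a ragged category to mix variants into")
      cat <- row$category
      h <- new("NSDFFile", path = out, compression = "none", level = 6L,
               mode = "append")
      pop <- "mixpop"
      if (cat == "event") {
        ev <- EventSet(pop, "extra", sources = "/mix/a",
                       times = list(c(0.1, 0.2)), unit = "s")
        .write_ragged(h, "event", pop, "extra", ev@sources, ev@times,
                      NULL, "s", "extra", NULL, "NANPADDED",
                      checkConsistency = FALSE)
      } else {
        rs <- RaggedSeries(pop, "extra", sources = "/mix/a",
                           values = list(c(1, 2)),
                           times = list(c(0.1, 0.2)), unit = "nA")
        .write_ragged(h, "nonuniform", pop, "extra", rs@sources,
                      rs@values, rs@times, "nA", "extra", "s", "NANPADDED",
                      checkConsistency = FALSE)
      }
    },
    R9 = .h5delete_attr(out, "/", "created"),
    R10 = .h5write_attr(out, "/", "created", "yesterday-around-noon"),
    R11 = {
      if (!"modeltree" %in% ix@modelKinds)
        stop("file has no target for rule R11: no model tree")
      groups <- character()
      rec <- function(g) {
        for (ch in .h5children(out, g)) {
          p <- paste0(g, "/", ch)
          if (identical(.h5kind(out, p), "group")) {
            groups <<- c(groups, p); rec(p)
          }
        }
      }
      rec("/model/modeltree")
      if (length(groups) < 2L)
        stop("model tree too small to create a duplicate uid")
      uid1 <- as.character(.h5attrs(out, groups[1L])$uid)
      .h5write_attr(out, groups[2L], "uid", uid1)
    },
    R12 = {
      row <- pick(d$category == "nonuniform" &
                  d$variant %in% c("VLEN", "NANPADDED"),
                  "a ragged nonuniform variable")
      tpath <- .time_path("nonuniform", row$population, row$variable)
      if (row$variant == "VLEN") {
        tms <- .vlen_read(out, tpath)
        if (!length(tms[[1L]])) stop("empty time row; cannot shorten")
        .vlen_write_row(out, tpath, 0L,
                        tms[[1L]][-length(tms[[1L]])])
      } else {
        lens <- .nan_row_lengths(.read_matrix(out, tpath))
        i <- which(lens >= 1L)[1L]
        rhdf5::h5write(NaN, out, tpath, index = list(lens[i], i))
      }
    })
  invisible(out)
}
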