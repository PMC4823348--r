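test_that("createNSDF lays out the level-1 groups and root metadata", {
  f <- h5tmp()
  h <- createNSDF(f, NSDFMetadata(title = "t", creator = "c"))
  expect_s4_class(h, "NSDFFile")
  a <- rhdf5::h5ls(f, recursive = FALSE)
  expect_true(all(c("data", "map", "model") %in% a$name))
  md <- readMetadata(openNSDF(f))
  attrs <- nsdf:::.h5attrs(f, "/")
  expect_true(all(c("title", "creator", "created", "software", "method",
                    "nsdf_version") %in% names(attrs)))
  expect_identical(md@title, "t")
  # create then immediately validate: an empty file is well-formed
  expect_true(conforms(validateNSDF(f)))
})

test_that("createNSDF overwrites by default and refuses non-NSDF appends", {
  f <- h5tmp()
  h <- createNSDF(f)
  addUniform(h, rand_uniform_block())
  h2 <- createNSDF(f)                    # overwrite: old content gone
  expect_identical(nrow(openNSDF(f)@datasets), 0L)
  # append mode reopens a conforming file
  h3 <- createNSDF(f, overwrite = FALSE)
  expect_identical(h3@mode, "append")
  plain <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(plain)
  withr::defer(unlink(plain))
  expect_error(createNSDF(plain, overwrite = FALSE), "not an NSDF file")
})

test_that("source scales are shared, idempotent and conflict-checked", {
  f <- h5tmp()
  h <- createNSDF(f)
  uids <- c("/model/modeltree/neuronA/soma", "/model/modeltree/neuronA/axon")
  p1 <- addSourceScale(h, "uniform", "neuronA", uids)
  expect_identical(p1, "/map/uniform/neuronA")
  expect_identical(as.character(rhdf5::h5read(f, p1)), uids)
  expect_identical(addSourceScale(h, "uniform", "neuronA", uids), p1)
  expect_error(addSourceScale(h, "uniform", "neuronA", rev(uids)),
               "different uids")
  expect_error(addSourceScale(h, "uniform", "x", c("/a", "/a")),
               "duplicate")
  expect_error(addSourceScale(h, "uniform", "x", character()), "nonempty")
  solo <- addSourceScale(h, "event", "solo", "/only")
  expect_identical(length(as.character(rhdf5::h5read(f, solo))), 1L)
  # two variables of one population share one scale object
  set.seed(1)
  mk <- function(var) UniformBlock("neuronA", var, uids,
                                   matrix(stats::rnorm(6), 2),
                                   unit = "mV", tstart = 0, dt = 1e-3)
  addUniform(h, mk("Vm"))
  addUniform(h, mk("Im"))
  expect_identical(nsdf:::.ds_scales(f, "/data/uniform/neuronA/Vm", 0L),
                   nsdf:::.ds_scales(f, "/data/uniform/neuronA/Im", 0L))
})

test_that("uniform blocks round-trip in both time modes", {
  set.seed(2)
  b <- rand_uniform_block("pop", "Vm", n = 2L, Q = 5L)
  f1 <- h5tmp(); f2 <- h5tmp()
  addUniform(createNSDF(f1), b, timeMode = "attrs")
  addUniform(createNSDF(f2), b, timeMode = "explicit")
  r1 <- readUniform(openNSDF(f1), "pop", "Vm")
  r2 <- readUniform(openNSDF(f2), "pop", "Vm")
  expect_identical(values(r1), values(b))
  expect_identical(values(r2), values(b))
  expect_equal(times(r1), times(r2))
  expect_equal(times(r1), uniformTimeAxis(0, 1e-3, 5))
  # smallest legal dataset
  f3 <- h5tmp()
  one <- UniformBlock("p1", "v", "/s", matrix(4.2, 1, 1), unit = "mV",
                      tstart = 0, dt = 1)
  addUniform(createNSDF(f3), one)
  expect_identical(values(readUniform(openNSDF(f3), "p1", "v")),
                   matrix(4.2, 1, 1))
  # missing unit refused
  f4 <- h5tmp()
  expect_error(addUniform(createNSDF(f4),
                          UniformBlock("p", "v", "/s", matrix(1, 1, 1),
                                       unit = "", dt = 1)),
               "unit")
})

test_that("appending columns equals one-shot writing", {
  set.seed(3)
  b <- rand_uniform_block("pop", "Vm", n = 3L, Q = 100L)
  f1 <- h5tmp(); f2 <- h5tmp()
  h1 <- createNSDF(f1)
  addUniform(h1, UniformBlock("pop", "Vm", sources(b),
                              values(b)[, 1, drop = FALSE], unit = "mV",
                              tstart = 0, dt = 1e-3))
  for (j in 2:100)
    appendUniform(h1, "pop", "Vm", values(b)[, j, drop = FALSE])
  addUniform(createNSDF(f2), b)
  r1 <- readUniform(openNSDF(f1), "pop", "Vm")
  r2 <- readUniform(openNSDF(f2), "pop", "Vm")
  expect_identical(values(r1), values(r2))
  expect_identical(times(r1), times(r2))
  # K = 0 is a no-op returning the current width
  expect_identical(appendUniform(h1, "pop", "Vm",
                                 matrix(numeric(), 3, 0)), 100)
  # shape mismatch
  expect_error(appendUniform(h1, "pop", "Vm", matrix(0, 2, 1)),
               "row count")
  # tstart/dt untouched by appending
  a <- nsdf:::.h5attrs(f1, "/data/uniform/pop/Vm")
  expect_equal(as.numeric(a$tstart), 0)
  expect_equal(as.numeric(a$dt), 1e-3)
})

test_that("appending to an explicit-time dataset requires times", {
  f <- h5tmp()
  h <- createNSDF(f)
  set.seed(4)
  addUniform(h, rand_uniform_block("p", "v", 2L, 4L),
             timeMode = "explicit")
  expect_error(appendUniform(h, "p", "v", matrix(0, 2, 2)),
               "supply matching 'times'")
  appendUniform(h, "p", "v", matrix(0, 2, 2), times = c(4e-3, 5e-3))
  r <- readUniform(openNSDF(f), "p", "v")
  expect_equal(ncol(values(r)), 6L)
  expect_equal(times(r), uniformTimeAxis(0, 1e-3, 6))
})

test_that("events round-trip identically in every variant", {
  set.seed(5)
  ev <- rand_event_set(n = 4L)
  got <- lapply(c("ONED", "VLEN", "NANPADDED"), function(v) {
    f <- tempfile(fileext = ".h5")
    on.exit(unlink(f))
    addEvents(createNSDF(f), ev, variant = v)
    readEvents(openNSDF(f), "pop", "spike")
  })
  for (g in got) {
    expect_identical(sources(g), sources(ev))
    expect_identical(times(g), times(ev))
  }
  f <- h5tmp()
  expect_error(addEvents(createNSDF(f), ev, variant = "NUREGULAR"),
               "not applicable")
})

test_that("nonuniform data round-trip in all four variants", {
  set.seed(6)
  shared <- rand_ragged_series("popS", shared = TRUE, M = 7L)
  perSrc <- rand_ragged_series("popP", shared = FALSE)
  f <- h5tmp()
  addNonuniform(createNSDF(f), shared, variant = "NUREGULAR")
  r <- readNonuniform(openNSDF(f), "popS", "Im")
  expect_equal(r@sharedTimes, shared@sharedTimes)
  expect_equal(values(r), values(shared))
  expect_error(addNonuniform(createNSDF(h5tmp()), perSrc,
                             variant = "NUREGULAR"), "shared")
  for (v in c("ONED", "VLEN", "NANPADDED")) {
    fv <- tempfile(fileext = ".h5")
    on.exit(unlink(fv), add = TRUE)
    addNonuniform(createNSDF(fv), perSrc, variant = v)
    rv <- readNonuniform(openNSDF(fv), "popP", "Im")
    expect_equal(values(rv), values(perSrc), info = v)
    expect_equal(times(rv), times(perSrc), info = v)
  }
  # single source in ONED: one dataset plus a one-row map table
  one <- RaggedSeries("solo", "Im", "/m/s1", values = list(c(1, 2)),
                      times = list(c(0.1, 0.5)), unit = "nA")
  fo <- h5tmp()
  addNonuniform(createNSDF(fo), one, variant = "ONED")
  map <- nsdf:::.read_map_table(fo, "/map/nonuniform/solo/Im")
  expect_identical(nrow(map), 1L)
  expect_true(rhdf5::H5Lexists(rhdf5::H5Fopen(fo,
    flags = "H5F_ACC_RDONLY"), map$data[1L]))
  rhdf5::h5closeAll()
})

test_that("NANPADDED values and times matrices are congruently padded", {
  set.seed(7)
  rs <- rand_ragged_series("pop", shared = FALSE, n = 4L)
  f <- h5tmp()
  addNonuniform(createNSDF(f), rs, variant = "NANPADDED")
  vals <- nsdf:::.read_matrix(f, "/data/nonuniform/pop/Im")
  tms <- nsdf:::.read_matrix(f, "/map/time/nonuniform_pop_Im")
  expect_identical(is.na(vals), is.na(tms))
})

test_that("static tables round-trip in both layouts", {
  f <- h5tmp()
  h <- createNSDF(f)
  set.seed(8)
  syn <- StaticTable("synapses", "connections", c("s0", "s1"),
                     data = data.frame(pre = c("/m/a", "/m/b"),
                                       post = c("/m/b", "/m/a"),
                                       weight = c(0.4, 0.7),
                                       stringsAsFactors = FALSE),
                     units = c("", "", "nS"), layout = "COMPOUND")
  addStatic(h, syn)
  morpho <- StaticTable("cells", "morphology", sprintf("c%d", 1:3),
                        data = stats::setNames(
                          as.data.frame(matrix(stats::runif(18), 3)),
                          c("x0", "y0", "z0", "x1", "y1", "z1")),
                        units = "um")
  addStatic(h, morpho)
  ix <- openNSDF(f)
  s1 <- readStatic(ix, "synapses", "connections")
  expect_identical(s1@layout, "COMPOUND")
  expect_identical(nrow(values(s1)), 2L)
  expect_identical(colnames(values(s1)), c("pre", "post", "weight"))
  expect_identical(unitString(s1), c("", "", "nS"))
  expect_identical(values(s1)$pre, c("/m/a", "/m/b"))
  s2 <- readStatic(ix, "cells", "morphology")
  expect_identical(s2@layout, "HOMOGENEOUS_2D")
  expect_identical(colnames(values(s2)),
                   c("x0", "y0", "z0", "x1", "y1", "z1"))
  expect_equal(as.matrix(values(s2)), as.matrix(values(morpho)),
               ignore_attr = TRUE)
  # index-valued fields with empty units pass strict validation
  expect_true(conforms(validateNSDF(f, strict = TRUE)))
})

test_that("model trees round-trip isomorphically", {
  f <- h5tmp()
  h <- createNSDF(f)
  root <- ModelNode("cellA", uid = "/model/modeltree/cellA",
                    ontology = "CNO:0000013",
                    attributes = c(kind = "pyramidal"),
                    children = list(
                      ModelNode("soma", uid = "/model/modeltree/cellA/soma",
                                mapRefs = "/map/uniform/cellA")))
  addModelTree(h, root)
  tr <- readModelTree(openNSDF(f))
  got <- tr@children[[1L]]
  expect_identical(got@name, "cellA")
  expect_identical(got@uid, root@uid)
  expect_identical(got@ontology, "CNO:0000013")
  expect_identical(unname(got@attributes["kind"]), "pyramidal")
  expect_identical(got@children[[1L]]@mapRefs, "/map/uniform/cellA")
  # duplicate uids across calls are rejected
  expect_error(addModelTree(h, ModelNode("other",
                                         uid = "/model/modeltree/cellA")),
               "uid")
  dup <- ModelNode("r", uid = "/r", children = list(
    ModelNode("k", uid = "/same"), ModelNode("k2", uid = "/same")))
  expect_error(addModelTree(createNSDF(h5tmp()), dup), "duplicate uid")
  sib <- ModelNode("r", uid = "/r2", children = list(
    ModelNode("k", uid = "/k1"), ModelNode("k", uid = "/k2")))
  expect_error(addModelTree(createNSDF(h5tmp()), sib), "sibling")
})

test_that("external model descriptions are embedded, referenced or linked", {
  f <- h5tmp()
  h <- createNSDF(f)
  addFileContents(h, list("network.xml" = "<neuroml/>",
                          "a/b/c.txt" = "hello"))
  expect_identical(as.character(rhdf5::h5read(
    f, "/model/filecontents/network.xml")), "<neuroml/>")
  expect_identical(as.character(rhdf5::h5read(
    f, "/model/filecontents/a/b/c.txt")), "hello")
  expect_error(addFileContents(h, list("/abs.xml" = "x")), "relative")
  addFileRefs(h, c("m1.xml", "m2.xml", "m3.xml"))
  expect_identical(as.character(rhdf5::h5read(f, "/model/filerefs/files")),
                   c("m1.xml", "m2.xml", "m3.xml"))
  # external link to a node of another HDF5 file
  tgt <- h5tmp()
  ht <- createNSDF(tgt)
  set.seed(9)
  addUniform(ht, rand_uniform_block("p", "v"))
  addExternalLinks(h, list(net = c(file = tgt, path = "/data")))
  expect_true(nsdf:::.h5exists(f, "/model/links/net"))
})

test_that("files written with and without compression read identically", {
  set.seed(10)
  b <- genTwoNeurons(seed = 3)
  fz <- h5tmp(); fn <- h5tmp()
  writeBundle(b, fz, eventVariant = "NANPADDED", compression = "gzip")
  writeBundle(b, fn, eventVariant = "NANPADDED", compression = "none")
  iz <- openNSDF(fz); in_ <- openNSDF(fn)
  expect_identical(values(readUniform(iz, "neuronA", "Vm")),
                   values(readUniform(in_, "neuronA", "Vm")))
  expect_identical(times(readEvents(iz, "neurons", "spike")),
                   times(readEvents(in_, "neurons", "spike")))
  expect_true(conforms(validateNSDF(fz)))
})
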