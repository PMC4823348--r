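test_that("the index enumerates the worked example and detects variants", {
  b <- genTwoNeurons(seed = 0)
  f <- h5tmp()
  writeBundle(b, f, eventVariant = "VLEN")
  ix <- openNSDF(f)
  d <- ix@datasets
  expect_identical(sum(d$category == "static"), 1L)
  expect_identical(sort(d$variable[d$category == "uniform"]),
                   c("Im", "Vm"))
  expect_identical(d$variant[d$category == "nonuniform"], "NUREGULAR")
  expect_identical(d$variant[d$category == "event"], "VLEN")
  expect_identical(ix@modelKinds, "modeltree")
  # empty conforming file: all categories empty
  fe <- h5tmp()
  createNSDF(fe)
  expect_identical(nrow(openNSDF(fe)@datasets), 0L)
  # not HDF5 / not NSDF
  txt <- tempfile(); writeLines("x", txt); withr::defer(unlink(txt))
  expect_error(openNSDF(txt), "not an HDF5 file")
})

test_that("written variants are detected as what was written", {
  set.seed(20)
  ev <- rand_event_set(n = 3L)
  for (v in c("ONED", "VLEN", "NANPADDED")) {
    f <- tempfile(fileext = ".h5")
    on.exit(unlink(f), add = TRUE)
    addEvents(createNSDF(f), ev, variant = v)
    expect_identical(openNSDF(f)@datasets$variant, v, info = v)
  }
})

test_that("explicit time scales take precedence over stale attributes", {
  set.seed(21)
  b <- rand_uniform_block("p", "v", 2L, 5L)
  f <- h5tmp()
  addUniform(createNSDF(f), b, timeMode = "explicit")
  nsdf:::.h5write_attr(f, "/data/uniform/p/v", "dt", 999)
  expect_warning(r <- readUniform(openNSDF(f), "p", "v"), "precedence")
  expect_equal(times(r), uniformTimeAxis(0, 1e-3, 5))
})

test_that("a dataset with neither timing description is an error", {
  set.seed(22)
  f <- h5tmp()
  addUniform(createNSDF(f), rand_uniform_block("p", "v"))
  nsdf:::.h5delete_attr(f, "/data/uniform/p/v", "tstart")
  nsdf:::.h5delete_attr(f, "/data/uniform/p/v", "dt")
  expect_error(readUniform(openNSDF(f), "p", "v"), "incomplete metadata")
})

test_that("broken ONED map rows surface as mapping errors", {
  set.seed(23)
  f <- h5tmp()
  addEvents(createNSDF(f), rand_event_set(n = 2L), variant = "ONED")
  broken <- corruptNSDF(f, "R7")
  withr::defer(unlink(broken))
  expect_error(readEvents(openNSDF(broken), "pop", "spike"),
               "broken mapping")
})

test_that("NANPADDED time/value mask mismatches surface as congruence errors", {
  set.seed(24)
  f <- h5tmp()
  addNonuniform(createNSDF(f), rand_ragged_series("pop", n = 3L),
                variant = "NANPADDED")
  bad <- corruptNSDF(f, "R12")
  withr::defer(unlink(bad))
  expect_error(readNonuniform(openNSDF(bad), "pop", "Im"), "congruence")
})

test_that("zero-event sources read back as empty, present entries", {
  ev <- EventSet("p", "spk", c("/m/a", "/m/b"),
                 times = list(numeric(), c(1, 2)))
  for (v in c("ONED", "VLEN", "NANPADDED")) {
    f <- tempfile(fileext = ".h5")
    on.exit(unlink(f), add = TRUE)
    addEvents(createNSDF(f), ev, variant = v)
    r <- readEvents(openNSDF(f), "p", "spk")
    expect_identical(lengths(times(r)), c(0L, 2L), info = v)
    expect_identical(sources(r), sources(ev), info = v)
  }
})

test_that("source-to-data resolution agrees between map route and scan", {
  b <- genTwoNeurons(seed = 5)
  for (v in c("VLEN", "ONED")) {
    f <- tempfile(fileext = ".h5")
    on.exit(unlink(f), add = TRUE)
    writeBundle(b, f, eventVariant = v)
    ix <- openNSDF(f)
    for (uid in c("/model/modeltree/neuronA/soma",
                  "/model/modeltree/neuronA",
                  "/model/modeltree/neuronB/dend")) {
      expect_identical(sourcesToData(ix, uid, useModelMap = TRUE),
                       sourcesToData(ix, uid, useModelMap = FALSE),
                       info = paste(v, uid))
    }
    expect_setequal(sourcesToData(ix, "/model/modeltree/neuronA/soma"),
                    c("/data/uniform/neuronA/Vm",
                      "/data/uniform/neuronA/Im"))
    expect_identical(sourcesToData(ix, "/no/such/uid"), character())
  }
})

test_that("column ranges stream with correctly offset time axes", {
  set.seed(25)
  b <- rand_uniform_block("p", "v", 2L, 20L)
  for (mode in c("attrs", "explicit")) {
    f <- tempfile(fileext = ".h5")
    on.exit(unlink(f), add = TRUE)
    addUniform(createNSDF(f), b, timeMode = mode)
    ix <- openNSDF(f)
    full <- readUniform(ix, "p", "v")
    whole <- readColumnRange(ix, "p", "v", 0, 20)
    expect_identical(values(whole), values(full))
    expect_equal(times(whole), times(full))
    h1 <- readColumnRange(ix, "p", "v", 0, 9)
    h2 <- readColumnRange(ix, "p", "v", 9, 20)
    expect_identical(cbind(values(h1), values(h2)), values(full))
    expect_equal(c(times(h1), times(h2)), times(full))
    z <- readColumnRange(ix, "p", "v", 4, 4)
    expect_identical(dim(values(z)), c(2L, 0L))
    expect_identical(times(z), numeric())
    expect_error(readColumnRange(ix, "p", "v", 5, 21), "out of bounds")
    expect_error(readColumnRange(ix, "p", "v", -1, 3), "out of bounds")
  }
})

test_that("foreign extras are tolerated when reading", {
  set.seed(26)
  f <- h5tmp()
  addUniform(createNSDF(f), rand_uniform_block("p", "v"))
  rhdf5::h5createGroup(f, "/userstuff")
  nsdf:::.h5write_attr(f, "/data/uniform/p/v", "my_note", "hello")
  r <- readUniform(openNSDF(f), "p", "v")
  expect_s4_class(r, "UniformBlock")
})
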