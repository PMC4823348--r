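test_that("the two-neuron fixture reproduces the stated counts", {
  b <- genTwoNeurons(seed = 0)
  m <- manifest(b)
  expect_identical(m$synapses, 2L)
  expect_identical(m$eventsA, 11L)
  expect_identical(m$eventsB, 13L)
  expect_identical(lengths(times(b@events[[1L]])), c(11L, 13L))
  expect_identical(nrow(values(b@static[[1L]])), 2L)
  expect_identical(length(b@modelTree@children), 2L)
  expect_identical(vapply(b@modelTree@children[[1L]]@children,
                          function(n) n@name, character(1L)),
                   c("dend", "soma", "axon"))
})

test_that("fixture generators are pure functions of the seed", {
  expect_equal(genTwoNeurons(seed = 7), genTwoNeurons(seed = 7))
  expect_equal(genHH(seed = 7), genHH(seed = 7))
  expect_equal(genBenchmark(seed = 7, scaleFactor = 0.01),
               genBenchmark(seed = 7, scaleFactor = 0.01))
  a <- genTwoNeurons(seed = 1); b <- genTwoNeurons(seed = 2)
  expect_identical(lengths(times(a@events[[1L]])),
                   lengths(times(b@events[[1L]])))   # same shapes
  expect_false(isTRUE(all.equal(times(a@events[[1L]]),
                                times(b@events[[1L]]))))  # different values
  # generators do not disturb the caller's RNG stream
  set.seed(99); x1 <- stats::runif(1)
  set.seed(99); invisible(genTwoNeurons(seed = 3)); x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("the HH fixture has one Vm source and a 2-row IChannel", {
  b <- genHH(seed = 0)
  expect_identical(manifest(b)$vmSources, 1L)
  expect_identical(nrow(values(b@uniform[[1L]])), 1L)
  ich <- b@uniform[[2L]]
  expect_identical(varName(ich), "IChannel")
  expect_identical(nrow(values(ich)), 2L)
  f <- tempfile(fileext = ".h5")
  withr::defer(unlink(f))
  writeBundle(b, f)
  expect_true(conforms(validateNSDF(f)))
  r <- readUniform(openNSDF(f), "channels", "IChannel")
  expect_identical(nrow(values(r)), 2L)
})

test_that("benchmark shapes scale proportionally with a floor of one", {
  b <- genBenchmark(seed = 0, scaleFactor = 0.01)
  m <- manifest(b)
  expect_identical(m$nDatasets, 1L)
  expect_identical(m$P, 1L)
  expect_identical(m$Q, 100L)
  expect_identical(dim(values(b@uniform[[1L]])), c(1L, 100L))
  b2 <- genBenchmark(seed = 0, scaleFactor = 0.02)
  m2 <- manifest(b2)
  expect_identical(m2$raggedRange, c(100L, 200L))
  lens <- unlist(lapply(b2@events, function(e) lengths(times(e))))
  expect_true(all(lens >= 100L & lens <= 200L))
  lensN <- unlist(lapply(b2@nonuniform, function(s) lengths(values(s))))
  expect_true(all(lensN >= 100L & lensN <= 200L))
  expect_error(genBenchmark(scaleFactor = 0), "scaleFactor")
  expect_error(genBenchmark(scaleFactor = 1.5), "scaleFactor")
})

test_that("written twoneurons bundles satisfy the manifest in every variant", {
  b <- genTwoNeurons(seed = 0)
  for (v in c("ONED", "VLEN", "NANPADDED")) {
    f <- tempfile(fileext = ".h5")
    on.exit(unlink(f), add = TRUE)
    writeBundle(b, f, eventVariant = v)
    ix <- openNSDF(f)
    ev <- readEvents(ix, "neurons", "spike")
    expect_identical(lengths(times(ev)), c(11L, 13L), info = v)
    expect_identical(nrow(values(readStatic(ix, "synapses",
                                            "connections"))), 2L)
    expect_identical(length(readNonuniform(ix, "neuronB",
                                           "Im")@sharedTimes),
                     manifest(b)$nonuniformM)
  }
})
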