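test_that("uniform time axis follows tstart + j*dt with 0-based columns", {
  expect_equal(uniformTimeAxis(0, 0.1, 1), 0)
  expect_equal(uniformTimeAxis(0, 0.1, 3), c(0, 0.1, 0.2))
  expect_equal(uniformTimeAxis(10, 0.25, 5)[5], 11)
  expect_equal(uniformTimeAxis(0, 1e-4, 0), numeric())
  expect_error(uniformTimeAxis(0, 0, 5), "positive")
  expect_error(uniformTimeAxis(0, -1, 5), "positive")
})

test_that("successive axis steps equal dt to within one ulp", {
  for (dt in c(1e-4, 0.1, 0.25, pi / 7)) {
    ax <- uniformTimeAxis(3.7, dt, 1000)
    ulp <- 2 * .Machine$double.eps * pmax(abs(ax[-1L]), dt)
    expect_true(all(abs(diff(ax) - dt) <= ulp))
  }
})

test_that("uids are '/'-joined absolute paths with an inverse", {
  expect_identical(makeUid(c("model", "modeltree", "neuronA", "soma")),
                   "/model/modeltree/neuronA/soma")
  expect_identical(makeUid("x"), "/x")
  comps <- c("a", "b9", "soma.1")
  expect_identical(uidComponents(makeUid(comps)), comps)
  expect_error(makeUid(character()), "nonempty")
  expect_error(makeUid(c("a", "")), "nonempty")
  expect_error(makeUid("a/b"), "separator")
})

test_that("makeUid is injective over a large corpus of distinct paths", {
  set.seed(11)
  corpus <- unique(lapply(seq_len(30000), function(i)
    sample(c(letters, "soma", "dend", "axon"),
           sample.int(4L, 1L) + 1L, replace = TRUE)))
  stopifnot(length(corpus) >= 10000)
  corpus <- corpus[seq_len(10000)]
  uids <- vapply(corpus, makeUid, character(1L))
  expect_identical(anyDuplicated(uids), anyDuplicated(corpus))
  expect_false(anyDuplicated(uids) > 0L)
})

test_that("the unit grammar accepts SI forms and normalises powers", {
  expect_identical(validateUnit("mV"), "mV")
  expect_identical(validateUnit("mS/cm^2"), "mS/cm^2")
  expect_identical(validateUnit("mS/cm2"), "mS/cm^2")
  expect_identical(validateUnit("s^-1"), "s^-1")
  expect_identical(validateUnit("kg*m/s^2"), "kg*m/s^2")
  expect_identical(validateUnit("ohm"), "ohm")
  expect_identical(validateUnit("Mohm"), "Mohm")
  expect_identical(validateUnit("", allowEmpty = TRUE), "")
  expect_error(validateUnit(""), "empty")
  expect_error(validateUnit("furlong"), "unknown unit")
  expect_error(validateUnit("µS"), "non-ASCII")
  expect_error(validateUnit("m//s"), "misplaced")
  expect_error(validateUnit("m*"), "operator")
  expect_true(all(isValidUnit(c("mV", "nA", "uS", "mS/cm^2", "ms", "Hz",
                                "mmol/L", "nS", "s", "K"))))
  expect_identical(isValidUnit(c("mV", "furlong", "")),
                   c(TRUE, FALSE, FALSE))
})

test_that("NaN padding is reversible and rejects payload/interior NaN", {
  expect_identical(nanPad(list(c(1, 2), 3)),
                   matrix(c(1, 3, 2, NaN), nrow = 2))
  eq <- list(c(1, 2), c(3, 4))
  expect_identical(nanPad(eq), rbind(c(1, 2), c(3, 4)))
  expect_identical(nanUnpad(matrix(c(1, 3, 2, NaN), nrow = 2)),
                   list(c(1, 2), 3))
  expect_identical(nanUnpad(matrix(NaN, 1, 3))[[1L]], numeric())
  expect_error(nanUnpad(matrix(c(1, NaN, 2), nrow = 1)), "interior NaN")
  expect_error(nanPad(list(c(1, NaN))), "reserved")
  set.seed(42)
  for (i in seq_len(50)) {
    rows <- rand_rows(sample.int(5L, 1L))
    expect_identical(nanUnpad(nanPad(rows)), rows)
  }
})
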