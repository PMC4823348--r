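test_that("container validity enforces the format invariants", {
  expect_error(UniformBlock("p", "v", c("/a", "/b"),
                            matrix(0, 3, 2), unit = "mV", dt = 1e-3),
               "rows")
  expect_error(UniformBlock("p", "v", "/a", matrix(0, 1, 2), unit = "mV",
                            dt = 0), "positive")
  expect_error(UniformBlock("p", "v", "/a", matrix(0, 1, 3), unit = "mV",
                            explicitTimes = c(0, 2, 1)), "increasing")
  expect_error(UniformBlock("p", "v", "/a", matrix(0, 1, 3), unit = "mV",
                            explicitTimes = c(0, 1)), "columns")
  expect_error(RaggedSeries("p", "v", c("/a", "/b"),
                            values = list(1:2, 1:3),
                            times = list(c(0, 1), c(0, 1)), unit = "nA"),
               "equal lengths")
  expect_error(RaggedSeries("p", "v", "/a", values = list(1:3),
                            times = list(c(0, 1, 1)), unit = "nA"),
               "strictly increasing")
  expect_error(RaggedSeries("p", "v", c("/a", "/b"),
                            values = list(1:2, 1:3),
                            sharedTimes = c(0, 1), unit = "nA"),
               "shared time axis")
  expect_error(EventSet("p", "v", "/a", times = list(c(2, 1))), "sorted")
  expect_silent(EventSet("p", "v", "/a", times = list(c(1, 1, 2))))
  expect_error(StaticTable("p", "t", c("a", "b"),
                           data = data.frame(x = 1), units = "mV"),
               "row count")
  expect_error(StaticTable("p", "t", "a",
                           data = data.frame(x = 1, y = 2),
                           units = c("", "nS", "mV"), layout = "COMPOUND"),
               "one unit entry per field")
  expect_error(ModelNode("a/b"), "separator")
  expect_error(NSDFMetadata(created = "not-a-date"), "ISO 8601")
  expect_silent(NSDFMetadata(created = "2014-06-01T12:00:00Z",
                             tstart = "2014-06-01T11:59:00+02:00"))
})

test_that("accessors expose sources, values and computed time axes", {
  b <- UniformBlock("p", "Vm", c("/a", "/b"), matrix(1:6, 2), unit = "mV",
                    tstart = 0.5, dt = 0.25)
  expect_identical(population(b), "p")
  expect_identical(varName(b), "Vm")
  expect_identical(sources(b), c("/a", "/b"))
  expect_equal(times(b), c(0.5, 0.75, 1.0))
  expect_identical(unitString(b), "mV")

  rs <- RaggedSeries("p", "Im", c("/a", "/b"),
                     values = list(1:3, 4:6), sharedTimes = c(1, 2, 3),
                     unit = "nA")
  expect_identical(times(rs), list(c(1, 2, 3), c(1, 2, 3)))

  ev <- EventSet("p", "spk", "/a", times = list(c(0.1, 0.4)))
  expect_identical(times(ev), list(c(0.1, 0.4)))
  expect_identical(lengths(values(rs)), c(3L, 3L))
})
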