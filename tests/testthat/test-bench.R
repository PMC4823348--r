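test_that("the benchmark harness fills every requested cell", {
  dir <- tempfile(); dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE))
  res <- runBench(scaleFactor = 0.01, reps = 2L,
                  categories = c("uniform", "event"),
                  variants = c("ONED", "VLEN"),
                  modes = "oneshot", dir = dir, seed = 0)
  cells <- unique(res[, c("category", "variant", "compression", "mode")])
  expect_identical(nrow(cells), (1L + 2L) * 2L)   # uniform + 2 variants
  expect_true(all(table(res$metric) == nrow(cells)))
  expect_identical(unique(res$repetitions), 2L)
  expect_true(all(!is.na(res$sd)))
  expect_true(all(res$value[res$metric == "size_bytes"] > 0))
  sz <- function(v, comp)
    res$value[res$category == "event" & res$variant == v &
              res$compression == comp & res$metric == "size_bytes"]
  expect_identical(sz("VLEN", "gzip"), sz("VLEN", "none"))
  expect_error(runBench(variants = "FANCY"), "unknown variant")
})

test_that("incremental benchmark writing equals one-shot content", {
  dir <- tempfile(); dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE))
  corpus <- genBenchmark(seed = 1, scaleFactor = 0.01,
                         categories = "event")
  f1 <- file.path(dir, "a.h5"); f2 <- file.path(dir, "b.h5")
  nsdf:::.bench_write(corpus, f1, "event", "ONED", "none", "oneshot", 5L)
  nsdf:::.bench_write(corpus, f2, "event", "ONED", "none", "incremental",
                      5L)
  pop <- population(corpus@events[[1L]])
  r1 <- readEvents(openNSDF(f1), pop, "spike")
  r2 <- readEvents(openNSDF(f2), pop, "spike")
  expect_identical(times(r1), times(r2))
})
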