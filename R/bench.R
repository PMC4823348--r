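# Benchmark harness: write time (one-shot vs incremental), read time and
# on-disk size for every requested (category, variant, compression) cell.

.bench_clock <- function() proc.time()[["elapsed"]]

#' Run the storage-variant benchmark
#'
#' Generates a seeded benchmark corpus (see [genBenchmark()]) and measures,
#' for every requested combination of data category, storage variant,
#' compression setting and writing mode, the wall-clock write time, the
#' wall-clock time of reading everything back, and the on-disk file size.
#' Uniform data are variant-free, so the variant column is `"-"` for them;
#' variable-length (VLEN) datasets cannot be compressed in HDF5, so their
#' gzip cells produce files identical in size to the uncompressed ones.
#' Incremental writing appends in `steps` batches (columns for uniform
#' data, per-source event/sample batches otherwise).
#'
#' @param scaleFactor corpus scale passed to [genBenchmark()]
#' @param reps number of repetitions per cell (mean and sd are reported)
#' @param categories,variants cells to measure
#' @param compression subset of `c("none", "gzip")`
#' @param modes subset of `c("oneshot", "incremental")`
#' @param steps number of append batches in incremental mode
#' @param seed corpus seed
#' @param dir directory for the scratch files
#' @return a data.frame with one row per (category, variant, compression,
#'   mode, metric) cell: columns `value` (the mean), `repetitions`,
#'   `mean` and `sd`
#' @examples
#' \dontrun{
#' runBench(scaleFactor = 0.02, reps = 2)
#' }
#' @export
runBench <- function(scaleFactor = 0.02, reps = 2L,
                     categories = c("uniform", "nonuniform", "event"),
                     variants = c("ONED", "VLEN", "NANPADDED"),
                     compression = c("none", "gzip"),
                     modes = c("oneshot", "incremental"),
                     steps = 10L, seed = 0, dir = tempdir()) {
  categories <- match.arg(categories,
                          c("uniform", "nonuniform", "event"),
                          several.ok = TRUE)
  bad <- setdiff(variants, c("ONED", "VLEN", "NANPADDED"))
  if (length(bad))
    stop("unknown variant name(s): ", paste(bad, collapse = ", "))
  compression <- match.arg(compression, c("none", "gzip"),
                           several.ok = TRUE)
  modes <- match.arg(modes, c("oneshot", "incremental"),
                     several.ok = TRUE)
  reps <- max(1L, as.integer(reps))
  corpus <- genBenchmark(seed = seed, scaleFactor = scaleFactor,
                         categories = categories)
  rows <- list()
  push <- function(category, variant, comp, mode, metric, samples) {
    rows[[length(rows) + 1L]] <<- data.frame(
      category = category, variant = variant, compression = comp,
      mode = mode, metric = metric, value = mean(samples),
      repetitions = length(samples), mean = mean(samples),
      sd = if (length(samples) >= 2L) stats::sd(samples) else NA_real_,
      stringsAsFactors = FALSE)
  }

  run_cell <- function(category, variant, comp, mode) {
    ws <- numeric(reps); rs <- numeric(reps); sz <- numeric(reps)
    for (r in seq_len(reps)) {
      f <- file.path(dir, sprintf("bench_%s_%s_%s_%s.h5", category,
                                  variant, comp, mode))
      t0 <- .bench_clock()
      .bench_write(corpus, f, category, variant, comp, mode, steps)
      ws[r] <- .bench_clock() - t0
      sz[r] <- file.size(f)
      t0 <- .bench_clock()
      .bench_read(f, category)
      rs[r] <- .bench_clock() - t0
      unlink(f)
    }
    push(category, variant, comp, mode, "write_s", ws)
    push(category, variant, comp, mode, "read_s", rs)
    push(category, variant, comp, mode, "size_bytes", sz)
  }

  for (category in categories) {
    vs <- if (category == "uniform") "-" else variants
    for (variant in vs)
      for (comp in compression)
        for (mode in modes)
          run_cell(category, variant, comp, mode)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(scaleFactor = scaleFactor, reps = reps,
                              steps = steps, seed = seed,
                              gzipLevel = 6L)
  out
}

# split 1:n into k contiguous batches
.batches <- function(n, k) {
  if (!n) return(list())
  k <- max(1L, min(k, n))
  split(seq_len(n), ceiling(seq_len(n) / (n / k)))
}

.bench_write <- function(corpus, f, category, variant, comp, mode,
                         steps) {
  h <- createNSDF(f, NSDFMetadata(title = "benchmark"),
                  compression = comp)
  if (category == "uniform") {
    for (b in corpus@uniform) {
      if (mode == "oneshot") {
        addUniform(h, b)
      } else {
        Q <- ncol(b@values)
        first <- .batches(Q, steps)[[1L]]
        head <- UniformBlock(b@population, b@variable, b@sources,
                             b@values[, first, drop = FALSE],
                             unit = b@unit, tstart = b@tstart, dt = b@dt,
                             tunit = b@tunit)
        addUniform(h, head)
        for (cols in .batches(Q, steps)[-1L])
          appendUniform(h, b@population, b@variable,
                        b@values[, cols, drop = FALSE])
      }
    }
    return(invisible(NULL))
  }
  sets <- if (category == "event") corpus@events else corpus@nonuniform
  for (s in sets) {
    if (mode == "oneshot") {
      if (category == "event") addEvents(h, s, variant = variant)
      else addNonuniform(h, s, variant = variant)
      next
    }
    cut_rows <- function(rows, pick)
      lapply(seq_along(rows), function(i)
        rows[[i]][pick[[i]]])
    picks1 <- lapply(lengths(if (category == "event") s@times else
                             s@values), function(n) .batches(n, steps))
    nb <- max(c(1L, lengths(picks1)))
    batch_idx <- function(i, k)
      if (k <= length(picks1[[i]])) picks1[[i]][[k]] else integer()
    for (k in seq_len(nb)) {
      pick <- lapply(seq_along(s@sources), batch_idx, k = k)
      if (category == "event") {
        chunk <- EventSet(s@population, s@variable, s@sources,
                          cut_rows(s@times, pick), unit = s@unit,
                          field = s@field)
        if (k == 1L) addEvents(h, chunk, variant = variant,
                               extendible = TRUE)
        else appendEvents(h, chunk)
      } else {
        tms <- times(s)
        chunk <- RaggedSeries(s@population, s@variable, s@sources,
                              cut_rows(s@values, pick),
                              times = cut_rows(tms, pick),
                              unit = s@unit, field = s@field,
                              tunit = s@tunit)
        if (k == 1L) addNonuniform(h, chunk, variant = variant,
                                   extendible = TRUE)
        else appendNonuniform(h, chunk)
      }
    }
  }
  invisible(NULL)
}

.bench_read <- function(f, category) {
  ix <- openNSDF(f)
  d <- ix@datasets
  for (i in seq_len(nrow(d))) {
    switch(d$category[i],
           uniform = readUniform(ix, d$population[i], d$variable[i]),
           nonuniform = readNonuniform(ix, d$population[i],
                                       d$variable[i]),
           event = readEvents(ix, d$population[i], d$variable[i]),
           static = readStatic(ix, d$population[i], d$variable[i]))
  }
  invisible(NULL)
}
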