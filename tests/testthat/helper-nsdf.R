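# shared helpers: temporary file paths and small random containers

h5tmp <- function() {
  f <- tempfile(fileext = ".h5")
  withr::defer(unlink(f), envir = parent.frame())
  f
}

# deterministic small ragged rows: n sources, lengths 0..maxlen
rand_rows <- function(n, maxlen = 8L, sorted = FALSE) {
  lapply(seq_len(n), function(i) {
    k <- sample.int(maxlen + 1L, 1L) - 1L
    x <- round(stats::runif(k, 0, 10), 6)
    if (sorted) sort(x) else x
  })
}

rand_event_set <- function(pop = "pop", var = "spike", n = 3L) {
  EventSet(pop, var, sources = sprintf("/m/%s/s%d", pop, seq_len(n)),
           times = rand_rows(n, sorted = TRUE), unit = "s")
}

rand_ragged_series <- function(pop = "pop", var = "Im", n = 3L,
                               shared = FALSE, M = 5L) {
  srcs <- sprintf("/m/%s/s%d", pop, seq_len(n))
  if (shared) {
    tt <- sort(stats::runif(M, 0, 10))
    RaggedSeries(pop, var, srcs,
                 values = lapply(seq_len(n), function(i) stats::rnorm(M)),
                 sharedTimes = tt, unit = "nA")
  } else {
    tms <- rand_rows(n, sorted = TRUE)
    # strictly increasing times required
    tms <- lapply(tms, function(t) unique(t))
    RaggedSeries(pop, var, srcs,
                 values = lapply(lengths(tms), stats::rnorm),
                 times = tms, unit = "nA")
  }
}

rand_uniform_block <- function(pop = "pop", var = "Vm", n = 2L, Q = 6L) {
  UniformBlock(pop, var, sources = sprintf("/m/%s/s%d", pop, seq_len(n)),
               values = matrix(stats::rnorm(n * Q), nrow = n),
               unit = "mV", tstart = 0, dt = 1e-3)
}

rand_static_table <- function(pop = "pop", name = "params", n = 3L,
                              layout = "HOMOGENEOUS_2D") {
  srcs <- sprintf("/m/%s/s%d", pop, seq_len(n))
  if (layout == "HOMOGENEOUS_2D") {
    StaticTable(pop, name, srcs,
                data = data.frame(Ra = stats::runif(n),
                                  Cm = stats::runif(n)),
                units = "F", layout = "HOMOGENEOUS_2D")
  } else {
    StaticTable(pop, name, srcs,
                data = data.frame(idx = as.numeric(seq_len(n)),
                                  g = stats::runif(n)),
                units = c("", "nS"), layout = "COMPOUND")
  }
}
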