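# one writer-produced file per relevant variant combination, reused below
make_twoneurons_file <- function(eventVariant, nonuniformVariant = "NUREGULAR",
                           compression = "none", seed = 0,
                           withModel = TRUE) {
  b <- genTwoNeurons(seed = seed)
  if (!withModel) b@modelTree <- NULL
  f <- tempfile(fileext = ".h5")
  writeBundle(b, f, eventVariant = eventVariant,
              nonuniformVariant = nonuniformVariant,
              compression = compression)
  f
}

test_that("every writer-produced layout conforms", {
  for (ev in c("ONED", "VLEN", "NANPADDED")) {
    for (nu in c("NUREGULAR", "NANPADDED")) {
      if (ev == "ONED" && nu != "NUREGULAR") next  # shared /map layout
      for (comp in c("none", "gzip")) {
        for (withModel in c(TRUE, FALSE)) {
          f <- make_twoneurons_file(ev, nu, comp, withModel = withModel)
          rep <- validateNSDF(f)
          expect_true(conforms(rep),
                      info = sprintf("%s/%s/%s/model=%s: %s", ev, nu,
                                     comp, withModel,
                                     paste(findings(rep)$message,
                                           collapse = "; ")))
          unlink(f)
        }
      }
    }
  }
})

test_that("each corruption triggers exactly its rule", {
  files <- list(
    R1 = make_twoneurons_file("VLEN"), R2 = make_twoneurons_file("VLEN"),
    R3 = make_twoneurons_file("VLEN"), R4 = make_twoneurons_file("VLEN"),
    R5 = make_twoneurons_file("VLEN"), R6 = make_twoneurons_file("NANPADDED"),
    R7 = make_twoneurons_file("ONED"), R8 = make_twoneurons_file("VLEN"),
    R9 = make_twoneurons_file("VLEN"), R10 = make_twoneurons_file("VLEN"),
    R11 = make_twoneurons_file("VLEN"),
    R12 = make_twoneurons_file("VLEN", "NANPADDED"))
  withr::defer(for (f in files) unlink(f))
  for (rule in names(files)) {
    out <- corruptNSDF(files[[rule]], rule)
    withr::defer(unlink(out))
    rep <- validateNSDF(out)
    fired <- unique(findings(rep)$rule[findings(rep)$severity == "error"])
    expect_identical(fired, rule, info = rule)
    expect_false(conforms(rep), info = rule)
  }
  expect_error(corruptNSDF(files$R1, "R99"), "arg")
})

test_that("validation is read-only and idempotent", {
  f <- make_twoneurons_file("VLEN")
  withr::defer(unlink(f))
  before <- tools::md5sum(f)
  r1 <- validateNSDF(f)
  r2 <- validateNSDF(f)
  expect_identical(tools::md5sum(f), before)
  expect_identical(findings(r1), findings(r2))
})

test_that("strict mode promotes unit-grammar findings to errors", {
  f <- tempfile(fileext = ".h5")
  withr::defer(unlink(f))
  h <- createNSDF(f)
  set.seed(30)
  b <- rand_uniform_block("p", "v")
  b@unit <- "parsec"
  suppressWarnings(addUniform(h, b))
  tolerant <- validateNSDF(f)
  expect_true(conforms(tolerant))
  expect_true("R3" %in% findings(tolerant)$rule)
  strict <- validateNSDF(f, strict = TRUE)
  expect_false(conforms(strict))
})

test_that("an unreadable path yields a single fatal finding", {
  rep <- validateNSDF(tempfile(fileext = ".h5"))
  expect_false(conforms(rep))
  expect_identical(nrow(findings(rep)), 1L)
})

test_that("model precedence follows modeltree > contents > refs > links", {
  mk <- function(kinds) {
    f <- tempfile(fileext = ".h5")
    h <- createNSDF(f)
    if ("modeltree" %in% kinds) addModelTree(h, ModelNode("m"))
    if ("filecontents" %in% kinds)
      addFileContents(h, list("m.xml" = "<x/>"))
    if ("filerefs" %in% kinds) addFileRefs(h, "m.xml")
    if ("links" %in% kinds) {
      tgt <- tempfile(fileext = ".h5")
      createNSDF(tgt)
      addExternalLinks(h, list(ext = c(file = tgt, path = "/data")))
    }
    f
  }
  cases <- list(
    list(kinds = c("modeltree", "filecontents"), sel = "modeltree"),
    list(kinds = c("filecontents", "filerefs", "links"),
         sel = "filecontents"),
    list(kinds = c("filerefs", "links"), sel = "filerefs"),
    list(kinds = "links", sel = "links"),
    list(kinds = character(), sel = "none"))
  for (cs in cases) {
    f <- mk(cs$kinds)
    withr::defer(unlink(f))
    pr <- resolveModelPrecedence(f)
    expect_identical(pr$selected, cs$sel,
                     info = paste(cs$kinds, collapse = "+"))
    expect_identical(pr$present, cs$kinds)
    expect_true(conforms(validateNSDF(f)))
  }
})

test_that("reports serialise to JSON", {
  f <- make_twoneurons_file("VLEN")
  withr::defer(unlink(f))
  j <- jsonlite::fromJSON(validationToJSON(validateNSDF(f)))
  expect_true(j$conforms)
  expect_identical(j$counts$error, 0L)
})
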