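Package: nsdf
Title: Read, Write and Validate Neuroscience Simulation Data Format Files
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An implementation of NSDF, an HDF5-based layout for the output
    of neuronal simulations. Provides typed containers for uniformly and
    nonuniformly sampled time series, spike-event sets, static parameter
    tables and hierarchical model trees; a writer supporting every storage
    variant of the format (regular 2D, per-source 1D, variable-length and
    NaN-padded ragged arrays) with streaming append and gzip compression; a
    variant-detecting reader; a rule-based conformance validator; seeded
    fixture generators for worked examples; and a benchmark harness
    comparing the storage variants for write time, read time and file size.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    rhdf5,
    jsonlite,
    stats,
    utils
LinkingTo: Rhdf5lib
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: DataImport, Infrastructure, ElectroPhysiology
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bench.R'
    'containers.R'
    'core.R'
    'fixtures.R'
    'hdf5-utils.R'
    'nsdf-package.R'
    'reader.R'
    'validator.R'
    'writer.R'
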