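---
title: "The NSDF layout: model, storage variants and design decisions"
author: "nsdf package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The NSDF layout: model, storage variants and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsdf)
```

## What the format models

Simulation output in neuroscience decomposes naturally into four
categories, and NSDF gives each a subtree under `/data`:

* **static** — values that do not change during a run: morphology
  coordinates, membrane parameters, synaptic connectivity and weights;
* **uniform** — time series sampled at a constant interval, the common
  case for fixed-step solvers;
* **nonuniform** — time series whose sampling instants must be stored
  explicitly, as produced by adaptive-step solvers;
* **event** — discrete occurrence times, primarily spikes, with a
  different count per source.

The central design commitment is that *every stored row must be
traceable to the model component it was recorded from*.  The `/map`
group carries this association: a 1D string dataset of unique
identifiers (uids) is attached to the row dimension of each 2D dataset
as an HDF5 *dimension scale* labelled `source`, so generic HDF5 tools
can recover the pairing without NSDF-specific knowledge.  Sampling
times live under `/map/time` and attach to the column dimension as a
scale labelled `time`.  Where data are stored as one 1D dataset per
source, dimension scales cannot express the reverse mapping, so an
explicit two-field table (`source`, `data`) provides it.

The `/model` group documents where the uids come from.  The fallback
*model tree* stores one HDF5 group per component with `uid` and
optional `ontology` attributes; alternatively the original model files
can be embedded as text (`filecontents`), referenced by path
(`filerefs`) or linked from other HDF5 files (`links`).  When several
descriptions coexist, readers interpret them in the fixed precedence
order *modeltree, filecontents, filerefs, links*
(`resolveModelPrecedence()`).  A file with no model description at all
is legal.

## Timing of uniform data

A uniform block stores `tstart` and `dt` (plus `tunit`) as dataset
attributes; the 0-based column `j` samples time `tstart + j * dt`
(`uniformTimeAxis()`).  This convention has two virtues: the end point
is unambiguous, and appending columns never requires touching the
attributes.  An explicit time axis may be stored instead (or in
addition) as a `time` dimension scale.  When both descriptions are
present the explicit scale wins; the reader additionally warns when the
two disagree by more than a relative `1e-9`, and the writer refuses
outright to produce a pair that disagrees by more than a relative
`1e-12`.  The paper-style 1-based sample index `n` corresponds to
`t_n = tstart + (n - 1) dt`; the package consistently exposes the
0-based column index.

## Ragged storage variants

Nonuniform and event data are ragged.  Four layouts are supported,
selected per call and detected structurally on read (`openNSDF()`):

* **NUREGULAR** (nonuniform only): all sources share one sampling-time
  axis, so the values form a regular 2D matrix with a shared 1D `time`
  scale.  A `RaggedSeries` is eligible exactly when its `sharedTimes`
  slot is set.
* **ONED**: one 1D dataset per source (level 5), each carrying a
  `source` attribute, plus the `source`/`data` map table; for
  nonuniform data each dataset also gets its own 1D time scale.
* **VLEN**: a single HDF5 variable-length dataset; for nonuniform data
  the sampling times are a second ragged dataset attached as a scale.
  Variable-length payloads are stored as 64-bit doubles (the C API
  imposes no narrower limit), and the `precision_fallback` escape hatch
  for bindings that cannot store doubles in ragged datasets is
  therefore never exercised here.
* **NANPADDED**: rows padded with trailing NaN into a regular matrix;
  for nonuniform data the time matrix is padded congruently, and the
  reader verifies that the two NaN masks agree.

NaN is reserved strictly as the padding sentinel: `nanPad()` rejects
payload NaN (and NA, which R stores as a NaN payload) rather than
letting it round-trip ambiguously, and `nanUnpad()` treats a valid
value after a NaN as a format error.  Within one file, all variables of
a category must use one consistent variant; the writer enforces this
and the validator flags violations (rule R8), while the reader simply
reads whatever each variable's layout indicates.

## Units

Physical datasets must carry a `unit` attribute.  The package
implements a closed UDUNITS-style subset: SI prefixes crossed with the
bases `m, s, A, V, S, F, ohm, mol, M, Hz, C, K, cd, kg, g, L`, combined
with `/`, `*` and integer powers.  `ohm` is written in full because the
SI symbol is non-ASCII.  Both `cm^2` and `cm2` are accepted on input
and normalised to the caret form.  Unknown units are a *warning* in the
writer and in tolerant validation, and an *error* in strict validation
— the format mandates the presence of units, not a particular
vocabulary, and real files contain domain-specific strings.  Fields
that carry no physical unit (indices, identifiers) take the empty
string, which is legal only in the per-field unit arrays of compound
tables.  No unit conversion or dimensional analysis is attempted.

## Writer choices

Several points are deliberately fixed where the format leaves room:

* **Paths, not object references.**  The ONED map table's `data` column
  and the model tree's `map` attribute store dataset *paths*.  Object
  references are poorly supported by several third-party HDF5 readers;
  the known risk of paths — breakage on rename — is closed by not
  offering a rename operation.
* **Deterministic time-scale names.**  Time datasets under `/map/time`
  are named `<category>_<population>_<variable>`, with a 0-based source
  index suffix for per-source ONED axes.  The format leaves the naming
  free; a deterministic scheme makes files reproducible byte-for-byte
  in structure and lets tests address the datasets directly.
* **Chunking and compression.**  Datasets that must grow (uniform
  blocks, anything written with `extendible = TRUE`) are chunked, with
  a default chunk of `(min(P, 64), min(Q, 1024))` in file order.
  One-shot uncompressed datasets are written contiguously: at small
  dataset sizes the chunk index is a measurable constant overhead with
  no benefit.  Gzip (level 6) applies a byte-shuffle filter first, the
  standard arrangement for floating-point payloads.  Variable-length
  datasets are always stored raw because HDF5 cannot compress them;
  requesting gzip for a VLEN write is honoured for everything else in
  the file and is a no-op for the ragged payload itself, which is why
  compressed and uncompressed VLEN files are identical in size.
* **NaN fill for extendible padded matrices.**  NANPADDED datasets
  created for appending set the HDF5 fill value to NaN so that rows
  extended by different amounts stay correctly padded.
* **Attribute strings are fixed-length.**  Variable-length string
  attributes cost one global-heap collection (4 KiB) each in HDF5
  1.10, which dominated file size for small files; fixed-length strings
  are stored inline in the object header.
* **Root metadata.**  `createNSDF()` writes the environment attributes
  (`title`, `creator`, `created`, `software`, `method`, `nsdf_version`,
  and the optional ones when supplied); `created`/`tstart`/`tend` must
  parse as ISO 8601.

Level-2 category groups are created lazily; the validator accepts both
their presence and their absence, since the format does not say whether
empty category groups must exist.

## Validator

`validateNSDF()` runs twelve rules with stable ids (R1 level-1 groups;
R2 category names; R3 unit attributes; R4 source-mapping resolvability;
R5 uniform timing; R6 NaN-suffix discipline; R7 ONED map-table
bidirectional consistency; R8 one variant per category; R9 mandatory
root metadata; R10 ISO 8601 timestamps; R11 model-tree uid uniqueness;
R12 value/time congruence of ragged nonuniform data).  Tolerant mode
(the default) reports unit-grammar deviations as warnings, mirroring
the format's "recommended" language; strict mode promotes them to
errors.  When `/map` is missing entirely (an R1 error), the per-dataset
mapping rules are implied and suppressed so that the report names the
root cause.  Missing mandatory root attributes are errors in both
modes; absent *optional* attributes produce no finding.  Whether the
column-label scale of homogeneous static tables is mandatory is
ambiguous in the format; the reader falls back to generated labels and
the validator does not flag their absence.  `corruptNSDF()` produces,
for each rule, a minimal targeted mutation of a conforming file, and
the test suite asserts that each mutation triggers exactly its rule.

## Fixtures and what they do (not) show

The generators are pure functions of their seed and never touch the
caller's RNG stream.

* `genTwoNeurons()` reproduces the two-neuron demonstration scenario with its
  fixed counts — 2 synapses, 11 and 13 spikes — and seeded values.  The
  uniform series default to `Q = 100` samples at `dt = 1e-4 s` and the
  shared nonuniform axis to `M = 47` points; the spike and sampling
  times are sorted uniform draws over a 10 s window, matching the time
  scale of a typical demonstration recording.  `M` and `Q` are not
  fixed by the format and are configurable.
* `genHH()` emulates a single-compartment Hodgkin-Huxley recording: one
  `Vm` source, a two-row `IChannel` block for the Na and K currents.
* `genBenchmark()` generates the benchmark corpus: at scale 1, 100
  uniform datasets of 100 sources by 10000 columns, and ragged row
  lengths drawn uniformly between 5000 and 10000.  `scaleFactor`
  shrinks every count proportionally (floored at 1).  Each category
  draws from its own seed substream so that the event corpus, say, is
  identical whether or not the other categories are generated.

The values are integrated noise or uniform draws — adequate for
exercising a storage format, not biophysically meaningful.  Passing
round-trip tests on these fixtures demonstrates correctness of the
layout and of serialisation, and nothing about the scientific validity
of any simulation.

## Benchmark harness

`runBench()` measures wall-clock write time (one-shot and incremental),
read time and on-disk size per (category, variant, compression) cell,
repeating each cell and reporting mean and standard deviation.
Incremental mode appends in batches (per-column for uniform data,
per-source contiguous slices otherwise; `steps` controls the batch
count).  Appending rewrites VLEN rows wholesale and must locate the NaN
boundary of every NANPADDED row, so those variants are expected to be
slow to extend — an inherent property of the layouts, not of this
implementation.  Timing magnitudes are hardware-dependent and are
reported, never asserted; the *size* relations between variants are
structural and are asserted in the acceptance tests on the event corpus
at `scaleFactor = 0.05` (the scale keeps the suite within an ordinary
desktop run; the relations are driven by padding waste, heap overhead
of ragged storage, and the incompressibility of random mantissas, all
of which are present at this scale).

## Problem sizes used by the test suite

Round-trip property tests use 200 seeded fixtures with 1-4 sources and
row lengths up to 9; the streaming test appends 100 single columns; the
size-property test runs the event benchmark at scale 0.05 (5 datasets,
5 sources, lengths 250-500).  These sizes were chosen to exercise every
code path, including zero-length rows and zero-width blocks, while
keeping the default suite fast enough to run habitually.

## Known limitations

* Simulator integrations, visualisation, experimental-data session
  structure, image/spatial data types and ontology resolution are out
  of scope.
* Embedded model descriptions are stored verbatim; they are never
  parsed, validated against their own schemas, or executed.
* One writer per file: there is no concurrency-safe multi-writer mode.
* External raw-binary wrapping of datasets is not provided; linking to
  other HDF5 files via `/model/links` is.
* The ordering of sources in ONED files follows the map-table rows;
  files from other writers may order differently, which the reader
  preserves rather than normalises.
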