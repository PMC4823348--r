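# nsdf

Read, write and validate **NSDF** (Neuroscience Simulation Data Format)
files from R.

## The problem

Neuronal simulations produce heterogeneous output: membrane potentials
sampled at a fixed solver step from thousands of compartments, currents
recorded under adaptive (variable) time steps, spike trains with a
different number of events per cell, and static tables such as
connectivity and biophysical parameters.  Sharing such data requires a
container that is efficient for large numeric arrays, self-documenting,
and — crucially — keeps an unambiguous mapping between every stored row
and the model component it was recorded from.

NSDF is an HDF5 layout built around that mapping.  A file has three
level-1 groups:

* `/data` — the recorded values, organised as
  `/data/<category>/<population>/<variable>` with the four categories
  `static`, `uniform`, `nonuniform` and `event`;
* `/map` — the source mappings: per-population *source dimension scales*
  (1D string datasets of unique identifiers attached to the row dimension
  of the data), source/data map tables for per-source 1D storage, and
  sampling-time scales under `/map/time`;
* `/model` — the model description: a fallback hierarchical *model tree*
  (one group per component, with `uid` and optional `ontology`
  attributes), embedded model files, external file references, or HDF5
  external links, interpreted in exactly that precedence order.

For a uniformly sampled block `V[i, j]` (source `i`, column `j`,
0-based), the sampling time is

```
t_j = tstart + j * dt
```

with `tstart`, `dt` and `tunit` stored as dataset attributes, or an
explicit `time` dimension scale that overrides the attributes when both
are present.  Ragged data (nonuniform samples, spike times) can be stored
in several *variants* with different trade-offs:

| variant     | layout                                              |
|-------------|-----------------------------------------------------|
| `NUREGULAR` | regular 2D matrix, one shared sampling-time scale (nonuniform only) |
| `ONED`      | one 1D dataset per source + a `source`/`data` map table |
| `VLEN`      | a single HDF5 variable-length (ragged) dataset      |
| `NANPADDED` | a regular 2D matrix padded with trailing NaN        |

Every dataset representing a physical quantity carries a `unit` attribute
in a UDUNITS-style grammar (`mV`, `nA`, `mS/cm^2`, ...).

The package provides S4 containers for all categories (`UniformBlock`,
`RaggedSeries`, `EventSet`, `StaticTable`, `ModelNode`), a writer
covering every variant with streaming append and gzip compression, a
variant-detecting reader, a 12-rule conformance validator, seeded fixture
generators and a benchmark harness comparing the variants.  A small
command-line tool (`exec/nsdf`) wraps validation, inspection, example
generation and benchmarking.

## Worked example

The canonical demonstration scenario: two three-compartment neurons
connected by two synapses; membrane potential and transmembrane current
recorded uniformly from neuronA's soma and axon; neuronB's current
recorded at 47 shared nonuniform time points; spike trains with 11 events
for neuronA and 13 for neuronB.

```r
library(nsdf)

bundle <- genTwoNeurons(seed = 0)
writeBundle(bundle, "two_neurons.h5", eventVariant = "VLEN")

(ix <- openNSDF("two_neurons.h5"))
#> NSDFIndex: two_neurons.h5
#>   event
#>     neurons/spike [VLEN]
#>   nonuniform
#>     neuronB/Im [NUREGULAR]
#>   static
#>     synapses/connections
#>   uniform
#>     neuronA/Im
#>     neuronA/Vm
#>   model: modeltree

readEvents(ix, "neurons", "spike")
#> EventSet 'neurons/spike': 2 source(s), event counts [11, 13]

vm <- readUniform(ix, "neuronA", "Vm")
vm
#> UniformBlock 'neuronA/Vm': 2 source(s) x 100 sample(s) [mV]
#>   tstart=0 dt=0.0001 s
head(times(vm), 3)
#> [1] 0e+00 1e-04 2e-04

validateNSDF("two_neurons.h5")
#> NSDF validation of 'two_neurons.h5': CONFORMS (0 error(s), 0 warning(s), 0 info)

sourcesToData(ix, "/model/modeltree/neuronA/soma")
#> [1] "/data/uniform/neuronA/Im" "/data/uniform/neuronA/Vm"
```

The event counts `[11, 13]` and the 2-row synapse table are the fixture's
defining counts; the index shows the variant detected for each variable,
and the last call resolves a model component to every dataset recorded
from it via the `/map` layer.

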