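# kinact

Upstream kinase activity analysis for kinome peptide array data.

Kinome arrays (e.g. the PamGene PamStation12 with PamChip serine-threonine
chips) measure the phosphorylation of ~140 immobilized reporter peptides by
the kinases in a tissue or cell lysate, imaged over a grid of pump cycles
and camera exposure times. The analytical challenge is to go from those
raw per-peptide signal kinetics to a statement about which *upstream
kinase families* are differentially active between two biological groups,
given that each kinase can phosphorylate many peptides and each peptide
can be phosphorylated by many kinases. `kinact` implements that whole
chain for R users: parsing, QC, kinetic modeling, differential
phosphorylation, random-sampling kinase scoring, and PPI network
expansion, plus a synthetic-data generator so everything is testable
offline.

## The statistic at the core

For each peptide *p* and well *w*, the end-point (last cycle) signal is
regressed on exposure time; the slope summarizes the phosphorylation
rate, and the **final signal** is

&nbsp;&nbsp;&nbsp;&nbsp;S(p, w) = log2(100 · slope(p, w))

Final signals are median-centered per chip (barcode), and the **log2 fold
change** LFC(p) between a comparison and a baseline group is computed
either across chips or within each chip (averaged over chips).
Differential peptide sets are extracted at several LFC cutoffs
(default 0.2, 0.3, 0.4; |LFC| ≥ cutoff).

For a differential set D of size *n* drawn from a QC-passing pool of *N*
peptides, and a kinase family K mapped to a subset of the pool, the
observed statistic is O(K) = #{p ∈ D : K maps to p}. The null is built
by drawing B random *n*-subsets of the pool uniformly without replacement
(B = 2000 by default) and recomputing the count each time, giving a
sampling mean μ(K) and standard deviation σ(K). The score is

&nbsp;&nbsp;&nbsp;&nbsp;Z(K) = (O(K) − μ(K)) / σ(K)

Z scores are computed per cutoff set and averaged (unweighted) into the
final score; families with |mean Z| ≥ 2 are called hits (over- or
under-represented by sign). Hits are then grown into an interaction
network using a protein–protein interaction edge list ("ball model":
node size = degree, node colour = averaged Z).

This sampling null conditions on the chip's peptide panel and on the set
size, so kinases that are globally promiscuous on the chip are not
mistaken for differentially active ones.

## Input format

`readCrosstab()` accepts the delimited crosstab export of a chip run
(tab or comma, auto-detected). The accepted layout is:

```
QuantType=Median_SigmBg  Version=...  Date=...      <- meta line (key=value)
Barcode      . . . .  B001  B001 ...                <- one column per well
Well         . . . .  A1    A2   ...
SampleName   . . . .  ctrl1 ctrl2 ...
Group        . . . .  F     M    ...                <- optional
ID  UniprotAccession  Sequence  Cycle  ExposureTime  <wells...>
PEP_001  P12345  RRLIEDAEYAARG  32  10  12.4  9.1 ...
```

The quantification type must be `Median_SigmBg` or `Mean_SigmBg`; the
five fixed columns identify the reporter peptide and the (cycle,
exposure-time) grid point, and every further column is one well. Signals
are taken verbatim (negative values are preserved until QC).

## Worked example

A complete run on a simulated chip in which the substrates of one kinase
family (ERK in the bundled synthetic mapping) are planted as
differentially phosphorylated:

```r
library(kinact)

mapFile <- system.file("extdata", "synthetic_stk_mapping.tsv",
                       package = "kinact")
erk <- subset(read.delim(mapFile), kinase == "ERK")$peptideId
panel <- simulateCrosstab(seed = 1)$manifest$normalPeptides

crosstab <- tempfile(fileext = ".txt")
sim <- simulateCrosstab(differentialPeptides = intersect(erk, panel),
                        lfc = 0.5, seed = 1, path = crosstab)

ds <- qcSteps(assignGroups(readCrosstab(crosstab), "group"))
qcReport(ds)
#> Kinome-array QC report
#>   negative points rescaled to baseline: 10
#>   saturated points removed:             0
#>   undetectable peptides removed:        12
#>   reference peptides removed:           11
#>   surviving peptides:                   121

model <- scaleModel(extractEndpoint(ds))      # fits, chip-norm, groups
diff  <- computeLFC(model, baseline = "Female", comparison = "Male")
sets  <- peptideSets(diff, c(0.2, 0.3, 0.4))

mapping <- loadMapping(mapFile,
                       pool = sort(unique(normalizedFits(model)$peptideId)))
scores <- scoreKinases(mapping, sets, iterations = 2000, seed = 42)
selectHits(scores)
#>   kinase    meanZ       direction
#> 1    ERK 10.94618 overrepresented
#> 2    JNK  2.64776 overrepresented
#> 3    P38  2.07767 overrepresented
```

The planted family comes back with a very large positive averaged Z
(observed substrate count ~6 null SDs above the sampling mean in every
cutoff set); JNK and P38 ride along because they share substrates with
ERK in the mapping — exactly the multi-mapping behaviour the sampling
null is designed to quantify. Growing the hits through the bundled
synthetic PPI:

```r
net <- buildKinaseNetwork(selectHits(scores), scores,
                          system.file("extdata", "synthetic_kinase_ppi.tsv",
                                      package = "kinact"))
net
#> KinaseNetwork: 10 kinases (3 hits), 16 edges (8 hit-incident)
head(nodeMetrics(net), 3)
#>   kinase degree isHit      meanZ
#> 1  BARK2      4 FALSE -0.7304423
#> 2    CDK      4 FALSE  0.9338080
#> 3    RSK      4 FALSE  1.8056413
```

`runPipeline()` wires all of the above (plus exports and logging) behind
a single YAML-configurable call, and `inst/scripts/kinact` exposes it as
a shell command (`kinact run --config run.yaml`, with `fixtures` and
`robustness` subcommands).

The files `inst/extdata/synthetic_stk_mapping.tsv` and
`synthetic_kinase_ppi.tsv` are simulator-generated stand-ins for curated
kinase–substrate and PPI extracts; real analyses should supply their own
mapping and edge list in the same two-column format.

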