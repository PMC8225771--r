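---
title: "Functional-gene T-RFLP profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-gene T-RFLP profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trflptools)
```

## The problem

Terminal restriction fragment length polymorphism (T-RFLP) fingerprints a
microbial community by PCR-amplifying a marker gene with a fluorescently
labelled primer, digesting the amplicons with a restriction enzyme, and
sizing the labelled **terminal restriction fragments** (TRFs) on a capillary
sequencer. For functional guilds that cannot be resolved by 16S rRNA
phylogeny — acetogenic bacteria profiled through the formyltetrahydrofolate
synthetase (FTHFS) gene of the Wood–Ljungdahl pathway are the motivating
case — T-RFLP of the functional gene remains an inexpensive way to track
community dynamics over long reactor time series.

Interpreting such fingerprints needs two parallel computations that this
package provides end to end:

* an **experimental (Ex)** branch: ingest instrument peak tables, remove
  background noise, convert fluorescence to relative abundance (RA), and bin
  peaks into operational TRF units (oTRFs);
* an **in silico (IS)** branch: tag taxonomically annotated reference
  sequences with the (degenerate) primers, digest them in silico, and bin
  the predicted fragments the same way;

followed by matching the two branches to propose candidate taxa per Ex oTRF,
and ordination of the oTRF tables.

## In silico digestion

### Degeneracy semantics

Both the primers (e.g. forward `CCNACNCCNNNNGGNGANGGNAA`) and reference
sequences may contain IUPAC ambiguity codes, and recognition patterns may
too (Hpy188III is `TCNNGA`). Each code denotes a *set* of bases, so "does
this window contain a site?" has two defensible answers, and the package
implements both:

* **guaranteed** (default): the window's base set is a subset of the
  pattern's base set at every position — every disambiguation of the
  sequence carries the site;
* **possible**: the sets intersect at every position — some disambiguation
  carries the site.

Guaranteed is the default because the primer tags contribute long runs of
`N`: under possible semantics every `N`-containing window would "match"
almost any pattern, manufacturing cut sites inside the tags. Internally each
residue is a 4-bit base set, so subset and intersection tests are two
bitwise operations; the test suite proves the scanner equal to a brute-force
regex oracle on concrete sequences and to exhaustive disambiguation
(intersection/union over all concrete realizations) on degenerate ones.
Patterns that are not their own reverse complement are scanned on both
strands; the two shipped enzymes (AluI `AG^CT`, Hpy188III `TC^NNGA`, REBASE
definitions, editable YAML) are reverse-complement palindromes.

### Amplicon model and terminal fragments

`tag_with_primers()` builds `fwd + insert + revcomp(rev)` — for the default
23-bp primers and a typical 588-bp insert, a 634-bp tagged amplicon.
`insilico_pcr()` offers a primer-anchored alternative for full-length
references: it binds the forward primer at the leftmost compatible window
(non-empty intersection per position) and the reverse primer at the leftmost
downstream window on the bottom strand; a failed binding is a regular
"no amplicon" value. Alignment-based trimming of references is deliberately
out of scope — primer anchoring is deterministic and dependency-free.

Since only the 5'-labelled fragment is detected, the terminal fragment
length is `first site start (0-based) + cut_offset`; a site-free amplicon
survives whole and is flagged `unrestricted`. Unrestricted fragments are
kept through binning (they appear in real profiles as bins near the full
amplicon length) but remain identifiable via the in silico profile.

## Binning into oTRF units

Capillary size calling is only accurate to about a base pair, so fragments
within ±`w` bp (default `w = 2`) are clustered into one operational unit.
`cluster_moving_average()`:

1. sorts the unique integer sizes;
2. chains successive sizes with gap ≤ `w`;
3. recursively splits any chain whose span exceeds `2w` at its largest
   internal gap (leftmost on ties);
4. labels each cluster with its abundance-weighted mean size, rounded to the
   nearest **even** integer (exact ties down);
5. merges clusters with colliding labels.

Even-lattice labels reflect how capillary-sized oTRFs are conventionally
reported, and the weighted mean keeps the label inside `[min − 1, max + 1]`
of the member sizes. Nearest-integer labelling is available via
`binning_config(rounding = "nearest-integer")` for users whose size
standards differ. The analysis size range (inclusive 50–640 bp by default,
matching a ~634-bp amplicon) is applied before clustering, and weights are
conserved through binning.

Two numerical caveats are worth stating plainly:

* binning can shift a fragment's reported size relative to its raw TRF by up
  to a couple of base pairs — which is why Ex↔IS matching (below) has a
  windowed fallback;
* re-binning a *label set* is **not** a closed operation: adjacent bins can
  legitimately carry even labels exactly `w` apart (sizes `{102, 105}` bin
  to labels `{102, 104}`), and a second pass would chain those. Each single
  bin is a fixed point of re-binning, and label sets whose pairwise gaps
  exceed `w` are stable, but global label-set idempotence cannot hold for
  any clustering that both chains at gap ≤ 2 and reports even labels. Treat
  oTRF labels as bin names, not as data to re-cluster.

`bin_profile()` computes bin boundaries on the size multiset pooled over all
samples and then aggregates per-sample weights within each bin. This is a
deliberate design choice: a label × sample matrix is only meaningful if a
label denotes the same fragment population in every column, and pooling also
stabilises labels against size-calling jitter (a single jittered peak that
rounds to an odd size would otherwise flip its sample-local label by ±2 bp
about 10% of the time at jitter σ = 0.4).

## Experimental peak processing

`read_peak_csv()` starts from the per-peak CSV exported by instrument
software (ABIF binary parsing is upstream of this package); column names are
configurable, rows without a numeric size are skipped with a logged count,
and negative heights are fatal. `select_channel()` keeps the labelled dye
(default `"B"`, the blue FAM channel), discarding the size-standard channel.

`noise_filter()` implements the iterative proportion-threshold family: every
peak below `min_proportion` (default 0.5%, configurable — published T-RFLP
noise procedures of this shape do not agree on one constant) of the current
per-sample total fluorescence is removed and the total recomputed until
stable. The procedure is deterministic, idempotent, and monotone in the
threshold; iteration count is capped (`max_iterations`, default 100) and the
filter refuses to empty a sample rather than silently return nothing.
`relative_abundance()` then rounds sizes half-away-from-zero to integer bp,
sums equal sizes, and scales each sample to 100%.

## Matching experimental to in silico profiles

For every Ex oTRF label `e`, `match_ex_to_is()` reports both

* **exact IS TRF hits**: reference fragments whose raw in silico size equals
  `e`; and
* **windowed IS oTRF hits**: all members of in silico oTRFs whose label lies
  within ±`w` of `e`.

Taxonomy (distinct non-NA phyla and genera; `NA` can optionally count as a
pseudo-taxon) is rolled up over the *active* set: exact hits when any exist,
otherwise the windowed hits — the fallback needed because binning shifts
sizes. The tool reports candidate sets only, never a single "best" taxon
call: fragment-length identity is not sufficient evidence for an exact
taxonomic assignment, and the output tables keep both hit counts
(per-fragment and per-unique-size) so users can judge ambiguity themselves.

## Ordination

`profile_distance()` computes Euclidean distances or Bray–Curtis
dissimilarity (`1 − 2Σmin/(Σx+Σy)`, via vegan) between sample columns, and
`pcoa()` performs classical scaling via `stats::cmdscale`, returning only
positive-eigenvalue axes (negative eigenvalues, expected for Bray–Curtis,
are dropped with their total magnitude reported). Axis signs are fixed so
the largest-magnitude coordinate is positive, making outputs byte-stable.
On Euclidean distances of centred data, PCoA equals PCA up to sign — one of
the closed-form checks in the test suite. Reactor covariates (VFA g/L,
CH4 %, CO2 %) are passed through to the coordinate export for external
overlay; NMDS and vector fitting are intentionally not reimplemented, being
off-the-shelf elsewhere.

## The simulator: what it emulates, and what it does not

`sim_config()` + `gen_reference_db()` + `gen_community_series()` +
`simulate_electropherogram()` produce a fully ground-truthed desk-scale
study, emulating a two-reactor design: a stable control (`R2`) and a
disturbed reactor (`R1`) in which a subset of taxa (default 5 of 20) rises
log-linearly to a peak fold change (default 6×) inside a disturbance window
(default timepoints 5–9 of 12) and recovers, while total VFA rises and
methane falls along the same trajectory.

Defaults and their reasoning:

* **planted TRFs**: even sizes in 60–600 bp, pairwise ≥ 8 bp apart — on the
  even label lattice so that a recovered bin's label equals its generating
  fragment size, and separated enough that distinct taxa never share a bin;
* **size-calling jitter** σ = 0.4 bp: the single-base uncertainty that
  motivates the ±2 bp window; jittered sizes round to within ±1 bp of truth
  almost surely;
* **amplification factor** lognormal with sdlog = 0.1: a modest per-peak
  PCR/injection bias, calibrated so the relative-abundance distortion it
  induces (Bray–Curtis ≈ 0.05 between truth and recovered profiles) stays
  well inside the 0.1 recovery tolerance the validation suite asserts;
* **noise peaks**: Poisson (mean 10) per sample at uniform sizes, with
  heights jointly scaled so their *total* stays below the 0.5% filter
  threshold — so the noise filter provably removes all of them and the
  suite's outcome is deterministic even though its values are stochastic;
* **community model**: Dirichlet-style gamma proportions (shape 1.5) with
  small multiplicative drift (log-sd 0.08), a moderately even community of
  the kind reactor marker-gene profiles show.

The simulator does **not** model PCR chimeras, pseudo-TRFs from anomalous
electrophoretic mobility, partial digestion, or multi-enzyme consensus.
Passing the end-to-end tests therefore shows the *pipeline arithmetic* is
faithful under realistic jitter and noise — not that taxonomic predictions
on real data are accurate, which fragment-length evidence alone cannot
guarantee (rare taxa below the noise threshold are also legitimately lost,
mirroring real detection limits).

## Problem sizes used in validation

The shipped test suite runs the scanner oracle on 1000 random 200-bp
concrete sequences per enzyme plus 200 degenerate sequences (≤ 6 ambiguous
positions) under exhaustive disambiguation; binning and noise-filter
properties on 1000 random multisets/peak sets; and the end-to-end recovery
experiment at 20 taxa × 12 timepoints × 2 reactors, asserting per-timepoint
Bray–Curtis ≤ 0.1 against truth, exact in silico matching of every
recovered bin, and positive silhouette separation of disturbance-window
samples from the control reactor. These sizes keep the whole suite
comfortably within a coffee break on one CPU while exercising every code
path at realistic scale.

## Known limitations

* Cut positions of bottom-strand-only sites are reported from the top-strand
  5' end of the site; for the palindromic enzymes shipped this is exact, for
  non-palindromic enzymes the labelled-fragment length convention should be
  checked against the enzyme's geometry.
* Exact Ex↔IS label matching presumes both branches use the same binning
  configuration; cross-enzyme or cross-study bin reconciliation is out of
  scope.
* The moving-average clustering is the published worked-example behaviour
  (chaining at gap ≤ w, largest-gap splitting, weighted-mean even labels);
  other T-RFLP binning tools make different choices and will produce
  different labels for the same peak lists.
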