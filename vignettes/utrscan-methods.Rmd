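---
title: "Scanning mRNA UTRs for thermodynamically exceptional structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning mRNA UTRs for thermodynamically exceptional structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

G/C-rich 5' untranslated regions often translate poorly, and a common
mechanistic hypothesis is that a discrete stem-loop element — rather than
diffuse overall structure — carries the repression. Distinguishing the two
requires asking, position by position, (i) where along the UTR the most
stable secondary structure sits, and (ii) whether that stability exceeds
what the local base composition already guarantees. `utrscan` packages the
computational side of that question as a reusable scanner: sliding-window
thermodynamic folding, dinucleotide-preserving shuffled nulls, a segment
z-score, centroid base-pair-probability profiling, mutant ddG comparison,
and cross-species conservation summaries. The worked material throughout is
the proximal 167 nt of the human TGF-beta1 5' UTR, which the package can
reconstruct offline from its packaged construct oligonucleotides
(`tgfb1_inserts()`), together with its five adenine-substitution mutants.

## The model

Secondary structures are pseudoknot-free sets of Watson-Crick or GU wobble
pairs with a minimum hairpin loop of 3 unpaired residues. Two quantities
are computed per sequence or window:

* the **minimum free energy** (MFE) `E` over all structures, with one
  witness structure in dot-bracket notation (Zuker-style dynamic
  programming);
* the **ensemble free energy** `G = -RT log Z`, where
  `Z = sum_s exp(-E_s / RT)` runs over *all* structures (McCaskill's
  partition function), together with the matrix of marginal pairing
  probabilities `p(i,j)`.

The **centroid pair set** at threshold 0.5 collects the individual pairs
with `p(i,j) > 0.5`; two pairs sharing a base cannot both exceed one half,
so the set is automatically conflict-free. `centroid_pairs()` refuses lower
thresholds for exactly that reason.

The **segment score** of a window is the z-score of its folding free
energy against `n` dinucleotide-preserving scrambles of the same window,

    s = (E - mean(E_scrambled)) / sd(E_scrambled),

computed for both the MFE and the ensemble energy from one shared null
set. Dinucleotide (not mononucleotide) conservation is the appropriate
null because stacking thermodynamics and genomic composition biases are
both dinucleotide effects; the shuffler (`dinucleotide_shuffle()`) samples
uniformly from the Eulerian walks of the dinucleotide multigraph
(Altschul-Erickson: a random last-exit-edge arborescence toward the
terminal residue, then random permutation of the remaining edges), so
conservation is exact in integer counts, and the first and last residues
are fixed. Duplicate members of a null set are reported
(`make_null_set()$duplicate_count`) but never resampled, which keeps the
sample unbiased; for windows of 30 nt or more of mixed composition,
100-member sets are duplicate-free in practice.

## Two backends, one contract

All folding goes through `fold_config()`:

* `backend = "reference"` — a self-contained Zuker MFE and McCaskill
  partition-function engine (C++), over a deliberately simplified
  nearest-neighbour model: stacking energy `-(h1 + h2)` from per-pair-type
  half-strengths (GC 1.7, AU 1.1, GU 0.6 kcal/mol), affine hairpin
  (`4.0 + 0.15 * (size - 3)`) and interior/bulge (`2.0 + 0.3 * size`)
  penalties, affine multiloops (`3.4 + 0.4 * branches + 0.1 * unpaired`),
  interior loops capped at 30 unpaired residues, no lonely-pair
  prohibition. Every algorithmic path of this engine is verified against
  an exhaustive structure enumerator on hundreds of random 8-12-mers to
  1e-9 (MFE, `Z`, and the full probability matrix), so it anchors all
  property tests. Its absolute kcal/mol values are *comparative*, not
  calorimetric.
* `backend = "thermodynamic"` — an adapter to the ViennaRNA `RNAfold`
  program (batched multi-FASTA invocations; base-pair probabilities parsed
  from the dot-plot output). This backend carries fitted Turner parameters
  and is the one to use when comparing against published kcal/mol values.

`parameter_set` selects the thermodynamic backend's energy table:
`"default"` is the installed RNAfold's own default (Turner 2004 for
ViennaRNA 2.x); `"turner1999"` loads the revision that ViennaRNA 1.x used.
The distinction matters: the TGF-beta1 analyses this package reproduces
were computed with a 1.x engine, and under Turner 2004 one mutant
(92/105A) retains a marginal residual hairpin (four pairs at p ~ 0.74)
that Turner 1999 — and the original analysis — does not predict. The
package's acceptance checks therefore run under `"turner1999"`; the
headline ddG values differ by under 1 kcal/mol between the two tables.

A related physical note: the reference model's constants are temperature
independent, so its `-RT log Z` can only drift *down* as `T` rises (the
derivative is minus the configurational entropy). Real melting — the
ensemble free energy rising toward zero as a hairpin opens — requires
enthalpy/entropy-resolved parameters and therefore appears only under the
thermodynamic backend. The test suite asserts each behaviour on the
backend where it belongs.

## Scanning and calibration

`scan_windows()` slides windows of every size in the spec (default 30-100
in steps of 2, matching the published protocol) along the sequence in
single-nucleotide steps, folding the native window and `n_null = 100`
scrambles per window. Conventions, fixed once:

* a window's reported **centre** is `start + floor((size - 1)/2)`;
* only fully contained windows are scanned;
* the **sample** (n-1) standard deviation enters the segment score (at
  n = 100 the population-sd alternative would shift |s| by ~0.5%,
  immaterial);
* degenerate nulls (sd = 0, e.g. homopolymeric windows) score 0 with an
  explicit flag rather than +/-Inf, keeping profiles plottable and honest;
* the native window's two energies share one null set, as a
  single-null-per-window design implies;
* per-window seeds derive from `(seed, size, start)` through a documented
  integer hash, so scans are reproducible and order-independent, and
  `n_null = 0` gives the plain energy-per-nucleotide profile cheaply.

`null_energy_profile()` emits the null counterpart of the
energy-per-nucleotide profile; extrema that co-locate with the native
profile's indicate composition-driven stability. On the reconstructed
167-mer, the 50-nt-window ensemble-energy-per-nucleotide minimum falls at
centre +85, inside the +77..+106 stem-loop element.

`calibrate_with_scrambles()` answers "are the native profile's spikes
unusual at all?" by scrambling the *whole* sequence, re-running the
identical windowed scan on each scramble, and placing the native minimum
segment score within the distribution of scramble minima. For a sequence
whose structure is composition-driven, the native minimum sits
unremarkably inside that distribution; for a planted-element synthetic it
falls in the extreme lower tail.

## Mutant comparison

`compare_construct()` folds reference and mutant with the partition
function, diffs their centroid pair sets, and reports
`ddg_ensemble = G_mutant - G_reference` (ensemble, following the
published convention; the MFE difference is emitted alongside). A-run
substitutions cannot pair internally (A-A is not a pair), so "the mutated
region is unpaired" is a meaningful structural readout.
`alternative_helix_report()` clusters gained pairs into maximal stacked
runs — `(i,j)` and `(i+1,j-1)` are neighbours — to expose compensatory
helices that partial mutations induce. The 167-nt insert, not a longer
context, is the comparison substrate, matching the cloned constructs.

## Conservation

`pairwise_similarity()` reports `100 * matches / aligned_length` (gap
columns in the denominator) from an optimal Needleman-Wunsch global
alignment (Biostrings; match 1, mismatch 0, gap open -3, gap extend -1 by
default, all exposed). The k-tuple heuristic of the commercial package
used in the original analysis is proprietary, so optimal-alignment
percent identity stands in; small deviations from heuristic-derived
percentages are expected. `project_region()` locates an element's
orthologous region by alignment projection; `conservation_report()`
combines whole-UTR similarity, element similarity and G/C content.
Full cross-species analyses need user-supplied accession FASTAs — the
package never fetches accessions, keeping runs hermetic and provenance
explicit.

## Synthetic benchmarks

`random_background()` samples iid or first-order-Markov sequences (the
Markov chain matches a target dinucleotide table and starts from its
stationary distribution — the same family of nulls the shuffler
preserves). `plant_hairpin()` overwrites a perfect stem-loop of chosen
stem length, loop length and arm G/C fraction, recording the exact planted
pair set as a truth annotation (JSON sidecar via `write_truth()`). These
generators emulate what the scanner assumes about real UTRs — local
composition bias plus a discrete thermodynamically stable element. They do
**not** emulate suboptimal-structure heterogeneity, pseudoknots,
G-quadruplexes, protein-bound or modified residues; a passing recovery
benchmark therefore demonstrates sensitivity of the method under its own
assumptions, not performance on arbitrary cellular RNA.

Benchmark sizes used by the shipped tests, chosen to exercise every code
path at desk scale: enumeration cross-checks on 8-12-mers (where
exhaustive enumeration is exact); planted 12-bp hairpins at position 91 of
200-mers whose backgrounds match the 167-mer insert's dinucleotide table,
50 seeded replicates, recovery judged as the global 50-nt-window
energy-minimum centre landing within +/-5 nt of the planted interval (the
observed rate meets the 80% regression floor); shuffle-uniformity checks
on a 10-mer with an exhaustively enumerable rearrangement set (20,000
draws within 5 standard errors of uniform).

## Numerical choices

* Partition functions use per-nucleotide scaling
  (`s = exp(-1.07 * beta * E_mfe / n)`), so whole-UTR-sized sequences do
  not overflow doubles.
* `RT = 0.0019872 kcal/(mol K) * T(K)`, default 37 C (310.15 K).
* Reference-backend base-pair probabilities use a direct outside
  recursion that is O(n^4) in the worst case; it is exact and fine up to
  a few hundred nucleotides, which covers windows and inserts. Full-length
  UTR probability matrices are better computed with the thermodynamic
  backend.
* MFE tracebacks re-derive decisions with a 1e-7 kcal/mol tolerance; ties
  yield one deterministic witness structure.
* Dot-bracket is the only structure serialisation; probability matrices
  serialise as sparse `(i, j, p)` triples with `p >= 1e-6`
  (`write_bppm()`).

## Known limitations

* The reference model's energies are didactic constants: use it for
  algorithmic guarantees, relative comparisons and nulls, never for
  absolute stability claims.
* Segment-score spikes are not multiple-testing-corrected significance
  calls, and the calibration deliberately reports an empirical quantile,
  not a p-value.
* Percent similarity from optimal global alignment is a surrogate for the
  heuristic aligner used in the original cross-species comparison.
* Pseudoknots, G-quadruplexes and RNA-RNA interactions are out of scope.
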