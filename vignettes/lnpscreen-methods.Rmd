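---
title: "Methods: analysing DNA-barcoded LNP delivery screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing DNA-barcoded LNP delivery screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnpscreen)
```

## The screen this package analyses

In a pooled barcoded-nanoparticle screen, dozens of chemically distinct
lipid nanoparticles (LNPs) are each formulated to carry a unique
single-stranded DNA barcode (plus a functional mRNA cargo), mixed, and
injected into reporter mice. Cells in which the cargo was functionally
delivered are sorted, their barcodes amplified by nested PCR and sequenced,
and the read counts per barcode reveal which formulations delivered. A
naked (unencapsulated) barcode is co-injected as a negative control, and an
aliquot of the injected mixture itself — the *input pool* — is sequenced to
measure each barcode's starting abundance.

`lnpscreen` implements the full computational side of such a screen:

1. **Barcode and scaffold design** — error-tolerant 8-nt barcode sets and
   the 91-nt amplicon scaffold that carries them.
2. **Library design** — combinatorial enumeration of formulations, the
   dynamic-light-scattering (DLS) quality gate, and pool dose accounting.
3. **Synthetic data** — a ground-truthed read simulator so every downstream
   stage is testable without sequencing data.
4. **Counting** — mismatch-tolerant extraction of barcodes and UMIs from
   FASTQ.
5. **Quantification** — input-normalized delivery, aggregation, ranking and
   the negative-control check.
6. **Enrichment** — component-level fold enrichment over the top/bottom
   deciles, with bootstrap intervals.

## Barcode and scaffold design

Barcodes are 8-nt sequences; the space of such sequences holds
$4^8 = 65{,}536$ codes, of which a screen uses well under 1%. The design
constraints that matter are *separation* and *diversity*:

* **Separation.** `generate_barcode_set()` guarantees a minimum pairwise
  Hamming distance, default `min_hamming = 3`. With distance ≥ 3, a read
  barcode observed with a single substitution is still uniquely nearest its
  true source, so the counting stage can assign at one mismatch without
  ambiguity (`min_hamming >= 2 * max_mismatch + 1`). The generator uses
  greedy rejection sampling under an explicit seed with a bounded number of
  attempts; infeasible requests fail loudly rather than returning a
  silently smaller set.
* **Diversity.** Amplicon libraries are low-complexity; if one base
  dominates a cycle, base-calling quality degrades ("sequence bleaching").
  We operationalise the published design intent as a testable rule: at
  every barcode position, no single base may occupy more than 75% of the
  set (`diversity_ceiling`, configurable). This is our own proxy — the
  original design rule is not published.

The full scaffold is a 91-nt single strand. Its exact segment map is not
published, so the layout is configuration-driven
(`scaffold_layout()`); the default, in order:

| segment            | length | content                                     |
|--------------------|-------:|---------------------------------------------|
| fwd_primer_region  | 20     | universal forward anchor (from primer set)   |
| barcode8           | 8      | the LNP's barcode                           |
| umi7               | 7      | degenerate 7-mer, one random draw/molecule  |
| probe_site         | 20     | fixed ddPCR probe site (default sequence)   |
| spacer             | 16     | fixed padding to 91 nt                      |
| rvs_primer_region  | 20     | reverse complement of the reverse anchor    |

The primer regions are *derived from the primer table*, not hard-coded: the
16 staggered nested-PCR primers ship with the package
(`inst/extdata/nested_pcr_primers.tsv`), and `load_primer_set()` computes
each orientation's universal anchor as the longest common 3'-terminal
subsequence, the shared sequencing adapter as the longest common 5' prefix,
and the per-primer stagger (0–7 nt) as the remainder. Staggers shift the
frame across the flow cell, which is the standard fix for low-complexity
amplicons; the simulator picks one of the 8 forward tails uniformly per
read, mirroring equimolar primer pooling. The 5'/3' phosphorothioate
modifications are carried as annotation only — they protect the oligo from
exonucleases but play no computational role.

## Library design and quality control

The default library is the Cartesian product of 8 piperazine-core
ionizable lipids × 2 cholesterol variants × 2 PEG-lipids × 4 molar ratios
with DOPE as the helper lipid: 128 formulations, enumerated in a stable
order and each assigned a barcode. The four ratios
(ionizable : cholesterol : PEG : helper, mol%) are 30:30:1:39,
35:46.5:2.5:16, 45:39.5:2.5:13 and 50:35:2.5:12.5; each must sum to 100.

The QC gate (`apply_qc()`) admits an LNP only if its intensity-average
hydrodynamic diameter lies **strictly** between 20 and 200 nm and the
particle is monodisperse. The source protocol states the bounds once as
strict inequalities and once as an inclusive range; we follow the strict
form (a particle of exactly 200 nm fails). Monodispersity is an
instrument-level judgement (a stable autocorrelation function with one
inflection point); the pipeline consumes it as a boolean column, or derives
it from a polydispersity index via `pdi <= 0.3` when only PDI is recorded —
the raw autocorrelation curve is not a pipeline input.

`build_pool()` collects the QC-passing LNPs plus the naked control barcode.
Dose accounting divides the total nucleic-acid dose by the number of LNP
*members*: 65 LNPs at 1.5 mg/kg total give 0.023 mg/kg per particle. The
control barcode is sequenced in the input (so it has an input proportion)
but is not an LNP, so it takes no share of the particle dose. Whether the
lab pools at equal mass or equal particle number is not recorded; the
default is a uniform barcode proportion with a configurable override.

## The synthetic-data model

The simulator exists so that counting, quantification and enrichment can be
validated against known truth. Its sampling law, per sorted-cell sample:

1. **Delivery propensities.** Each LNP × cell type gets a relative delivery
   weight drawn log-normally (`propensity_sdlog`, default 1) — pooled-screen
   delivery spans orders of magnitude, which a log-scale model captures.
   Component effects (e.g. one ionizable lipid × 10) multiply the weights
   of matching LNPs. The naked control's weight is set to
   `control_factor` (default 0.1) × the per-cell-type minimum LNP weight,
   encoding the biological expectation that free DNA enters cells worst of
   all; the *default* factor keeps it strictly lowest by construction, and
   the end-to-end tests check that this re-emerges through the whole noisy
   pipeline, not that it was inserted.
2. **Molecules.** Template molecules are drawn multinomially with
   probability ∝ input proportion × propensity. The molecule budget is
   `depth / mean_reads_per_molecule` (default 10 reads per template), so
   sampling noise is dominated by the molecule draw — as in a real library
   where PCR amplifies a bounded number of captured templates.
3. **UMIs.** Each molecule receives a fresh random 7-mer in the scaffold's
   degenerate region. We treat the published "7 random nucleotides to
   monitor PCR bias" as a UMI, the standard operationalization.
4. **PCR bias.** Each molecule gets a log-normal amplification factor
   (`pcr_bias_sd`, default 0.5); the sample's reads are allocated across
   molecules proportionally. Bias therefore multiplies *reads*, not
   *molecules*, which is why distinct-UMI counts are insensitive to it — a
   property the tests assert.
5. **Read structure and errors.** A read is a uniformly chosen staggered
   forward-primer tail followed by the full 91-nt scaffold, with i.i.d.
   substitution errors at `error_rate` (default 0.005) and constant
   quality strings. Reads are single-end and indel-free by default — a
   documented simplification; real MiniSeq data would add quality-dependent
   errors and occasional indels, and the counter's anchor scan is
   substitution-only, so indel-rich data would lower its assigned fraction.

What the simulator deliberately does **not** model: FACS sorting
efficiency, mouse-to-mouse biology, reporter-recombination kinetics, or
tissue composition. Passing tests therefore demonstrate that the *analysis*
recovers what the *sampling model* planted — they do not validate the
biology of any particular screen.

A counts-level fast path (`simulate_counts()`) applies steps 2 and 4
without constructing read strings; it is used for Monte-Carlo studies of
the rank-based statistics, where the FASTQ and extraction layers are not
under test (those layers have their own end-to-end checks).

## Counting

`count_sample()` streams a FASTQ through three steps:

1. **Anchor location.** The forward anchor is searched within the first
   `adapter + max stagger + anchor` bases, exact first, then allowing up to
   `max_mismatch_anchor` substitutions (default 1); fewest mismatches win,
   leftmost on ties. Unanchored reads are optionally retried
   reverse-complemented. The scan is Biostrings' mismatch-tolerant
   C matcher.
2. **Extraction.** Barcode and UMI are sliced at layout-defined distances
   from the anchor end; reads too short are unassigned.
3. **Assignment.** Exact barcode matches win; otherwise the unique member
   within Hamming distance 1 (a precomputed neighbourhood map). If a
   barcode set is too tight for the requested tolerance the counter forces
   exact matching with a warning rather than guessing among ambiguous
   neighbours.

Raw read counts — not UMI-collapsed counts — feed normalized delivery,
matching the original analysis, which normalized raw sequencing counts;
distinct-UMI counts are reported as PCR-bias QC (`counting_qc()`): the
reads-per-UMI ratio is the amplification monitor the degenerate region
exists for. UMI collapse is exact 7-mer matching; at 7 nt (16,384 states)
directional network collapse would add complexity without changing the
screen-level statistics, though 7-mer collisions do merge a small fraction
of molecules at high per-barcode molecule counts.

The counter maintains an exact conservation invariant
(assigned + unassigned = total) and, on error-free simulations, reproduces
the simulator's per-barcode read and distinct-UMI counts identically; an
independent naive quadratic matcher (every read × every barcode,
full-string Hamming) must agree with it read-for-read.

## Normalized delivery

For a sample with counts $c_i$ and input counts $c^{in}_i$ over the $N$
pool barcodes:

$$p_i = \frac{c_i}{\sum_j c_j}, \qquad q_i = \frac{c^{in}_i}{\sum_j c^{in}_j},
\qquad d_i = \frac{p_i / q_i}{\sum_j p_j / q_j}.$$

Within-sample proportions are corrected by the barcode's share of the
injected pool, then rescaled so each sample column sums to 1. The source
describes the two normalizations (within-sample proportion; normalization
to the injected mixture) without fixing their composition; this order is
one consistent reading, isolated in a single function so alternatives are
swappable. Whether the original analysis rescaled after input correction
is also not stated; we rescale, which fixes the column sum at 1 and makes
columns comparable. A pseudocount of 0.5 (configurable, including off) is
added to every barcode in both tables before forming proportions: it
prevents division by zero for input dropouts and stabilizes log displays;
under the default depths it shifts $d_i$ negligibly.

Aggregation over a sample grouping is the arithmetic mean of the normalized
columns (optional weighting by sorted-cell counts is exposed but off —
equal weighting matches "averaged across all samples"). Ranks are ordinal
(1 = highest delivery) with ties broken by barcode ID, so they are always a
permutation. `control_check()` verifies that the naked control aggregates
strictly lowest and reports the margin to the next-lowest barcode.

## Fold enrichment

The structure–function statistic asks: is a component level (a particular
ionizable lipid, cholesterol, PEG-lipid or molar ratio) over-represented
among the best LNPs? With the screened LNPs ranked by aggregated delivery
(control excluded):

* the **decile** is the best (or worst) $k = \max(1,
  \operatorname{round}(0.10\,N))$ LNPs, round-half-up, so $N = 65$ gives
  $k = 7$;
* **fold enrichment** of a level is its fraction of the decile divided by
  its fraction of the whole *screened* library (the 65, not the designed
  128 — expected fractions must describe the population the decile is drawn
  from).

The source calls this "the odds that a material is found in the top or
bottom 10% … relative to random chance" without a printed formula; we
implement the ratio of fractions as the default and expose a true 2×2
odds-ratio variant (`statistic = "odds_ratio"`), since "odds" is used
informally. Under the ratio definition the expected-fraction-weighted sum
of folds over one axis's levels is exactly 1, folds are invariant to any
strictly monotone transform of the delivery values, and the mean fold under
random rank permutations is exactly 1 — three invariants the test suite
asserts.

Point folds come with percentile bootstrap intervals
(`bootstrap_enrichment()`): sample columns are resampled with replacement,
the aggregate → rank → decile → fold chain is recomputed, and the 2.5/97.5
percentiles are reported. The original analysis reports point folds only;
the interval is this package's addition, and degenerate inputs (identical
samples) collapse it to zero width at the point fold.

## Numerical and design choices

* **Decile size** uses round-half-up with a floor of 1 (base R `round()`
  is banker's rounding, which would give $k=6$ at $N=65$).
* **Ties** everywhere break by barcode/LNP ID, making every ranked output
  deterministic.
* **Seeds** are explicit arguments; every generator runs in a private RNG
  stream and restores the caller's state, and full pipeline runs with the
  same configuration are byte-identical.
* **Strict QC boundaries**, the **pseudocount**, the **control's dose
  exclusion**, and **uniform pool proportions** are the open design points
  discussed above; each is configurable.
* The phrase "over 4 (65,536) distinct barcodes" in the source drops an
  exponent; `barcode_space_size()` implements $4^L$.

## Problem sizes used in the checks

The validation suite runs the screen at its real shape — 128 designed
formulations, 65 screened LNPs plus a control, 3 cell types × 3 mice —
with per-sample depths chosen per check: the oracle-equivalence comparison
uses 10,000 reads; delivery recovery uses the full 10^5-read depth
(Spearman ρ ≥ 0.9 against truth); the negative-control property is
replicated over 100 seeds at 10^4 reads per sample, a depth at which the
control's margin is still large (the statistic is depth-robust well below
that); null calibration uses 10,000 rank permutations; and the
component-effect power check runs 200 counts-level screens at depth 10^5.

## Known limitations

* Substitution-only error model and anchor scan; indels are neither
  simulated nor tolerated.
* Exact-match UMI collapse; no directional clustering.
* No base-quality-aware assignment (quality strings are parsed but unused).
* The enrichment bootstrap resamples samples, not mice; with few mice the
  interval understates between-animal variance.
* Real screens add biological and sorting variance the simulator does not
  model; simulator-based guarantees are about the analysis, not the assay.
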