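---
title: "Scanning cancer cohorts for regulatory mutations that alter TF binding"
author: "regmutscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning cancer cohorts for regulatory mutations that alter TF binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmutscan)
```

## The problem

Most somatic mutations in cancer genomes fall outside coding regions.  A
non-coding SNV can matter when it lands in a regulatory element and changes
how strongly a transcription factor (TF) binds: it can destroy an existing
binding site or create a new one.  Any single patient carries thousands of
SNVs, and per-variant binding predictors return dozens of candidate TFs per
variant, so the per-variant view does not scale to a cohort.

`regmutscan` takes the cohort view.  It looks for *mutation hotspots* —
places where somatic SNVs from several patients cluster in the promoter of a
differentially expressed gene — scores every patient's combined local
mutations as one *mutation block* with a biophysical TF-binding model, and
asks, per TF, whether the cohort's binding changes are stronger than
expected under randomized background mutations.  The output per block is a
short list of TFs with a direction (site creation or destruction), a
Bonferroni-corrected rank-sum p-value, and per-patient effect sizes suitable
for a heatmap.

## The biophysical binding model

A TF is described by a position-specific affinity matrix (PSAM): an
$M \times 4$ matrix $w$ whose entry $w_{j,a}$ is the binding energy
contribution of base $a$ at motif position $j$ (lower = stronger).  The
binding energy of an $M$-mer window $S$ is the independent-site sum
$E(S, w) = \sum_{j} w_{j, S_j}$, and the expected occupancy of a sequence of
length $N$ is the statistical-mechanics sum over sliding windows

$$P(S, w, \mu) \;=\; \sum_{i=0}^{N-M} \frac{1}{1 + e^{E(S_{i:i+M},\, w) - \mu}},$$

where the chemical potential $\mu$ encodes the TF's effective nuclear
concentration.  Low $\mu$ (scarce TF) makes the logistic sharp, so only
near-consensus sites are occupied; high $\mu$ saturates everything.  Because
the relevant concentration is unknown, occupancies are evaluated over a
ladder of chemical potentials, by default
$\mu \in \{0, -10, -13, -15, -18, -20\}$, spanning the dynamic range over
which verified regulatory variants alter occupancy.

By default both strands are scanned (`strand = "both"`): occupancy is
physically strand-agnostic, and the forward-only variant is kept for testing
the single-strand equation directly.  Windows containing `N` contribute zero
occupancy; dropping whole regions instead would silently discard hotspots.

The scanner uses the identity
$e^{E - \mu} = e^{-\mu} \prod_j \left(e^{w_{j,a}}\right)^{S_{j,a}}$ with
$e^{w_{j,a}}$ and $e^{-\mu}$ precomputed once per (PSAM, $\mu$), so no
exponential is evaluated inside the sliding window.  The compiled scanner is
verified against a naive double-loop implementation to $10^{-10}$ relative
error in the test suite.

## dbA and the binding-change score

Raw occupancy grows with sequence length and composition, so binding
strength is measured *above background*: the differential binding affinity

$$\mathrm{dbA}(S) \;=\; \max\!\Big(0,\; P(S) - \overline{P(\mathrm{shuffle}(S))}\Big),$$

the occupancy minus the mean occupancy of `n_shuffles` (default 100)
mononucleotide-composition-preserving shuffles of the same sequence, floored
at zero.  Shuffles are drawn from a private, seeded RNG stream (one stream
per block, shared across PSAMs and chemical potentials), which makes every
score deterministic and lets the reference and alternate sequence of a block
share the same shuffle pattern — a patient whose alternate equals the
reference scores exactly zero.

A mutation's effect on one TF is the shifted differential binding affinity

$$\delta\mathrm{dbA}(S_{\mathrm{ref}}, S_{\mathrm{alt}}) \;=\;
\mathrm{dbA}(S_{\mathrm{alt}}) - \mathrm{dbA}(S_{\mathrm{ref}}),$$

positive for binding-site creation, negative for destruction, antisymmetric
by construction.  Per (patient, TF), $\delta$dbA is computed at every
$\mu$ of the ladder and aggregated by arithmetic mean; the mean is
order-independent, preserves antisymmetry, and yields the one-cell-per-
patient summary the effect-size heatmap needs.  The per-$\mu$ tensor is
retained in the `delta_set` so alternative aggregations can be explored.

## From cohort data to mutation blocks

1. **Differential expression.**  Gene-level RPKM values of patients are
   compared with normal samples by the two-sample Kolmogorov–Smirnov test
   (`ks_differential_genes`), two-sided, on RPKM directly — the test is rank
   based, so no transformation or pseudo-count is applied and zero-RPKM ties
   are left to the empirical CDF.  The default keeps genes at raw
   $p < 0.05$ with **no** multiple-testing correction: RPKM-level screening
   is noisy and the selection is only a gate for the downstream scan;
   Bonferroni is available as an option, and an external gene list can be
   supplied instead (mutually exclusively).  Both up- and down-regulated
   genes are retained, since binding changes in either direction are of
   interest.
2. **Promoter windows.**  One window per gene around the TSS, default 2000
   bp upstream to 100 bp downstream, using the outermost (5'-most) TSS when
   a gene has several transcripts so the gene-to-region map stays
   one-to-one.  Coordinates are 0-based half-open internally; 1-based input
   positions are converted on read, and every mutation's ref allele is
   validated against the genome (the run aborts above a 1% mismatch rate,
   the signature of a genome-build mix-up).
3. **Hotspots.**  Within each (merged) promoter region, mutations are
   single-linkage clustered with inter-mutation gap at most `max_gap`
   (default 30 bp).  A cluster is a hotspot when it has at least
   `min_mutations` (2) mutations from at least `min_patients` (2) distinct
   patients — recurrence across patients is required.  The defaults admit
   2-SNV blocks, which known cohorts do produce, and every knob is
   configurable.  The block region is the cluster span plus `flank`
   (default 25 bp) of context on each side so motif windows can straddle
   cluster edges, clipped to the promoter region.
4. **Blocks.**  The reference sequence comes from the reference genome over
   the hotspot region; each patient with mutations in the region gets one
   alternate sequence carrying *all* of that patient's SNVs there.  Only
   somatic SNVs are used: indels, multi-allelic records and germline
   variants are out of scope, and sequencing depth QC (e.g. a minimum depth
   of 30 in promoters for robust calls) is assumed to have happened
   upstream.

## Background mutation blocks and significance

For each patient block, `n_background` (default 2000) background blocks are
generated under three constraints: (a) each background block has exactly the
patient block's length and per-patient mutation-count multiset — one
alternate per patient count, carrying exactly that many substitutions — so
the background $\delta$dbA sample has the same structure as the patient
sample; (b) background reference windows are drawn uniformly from the same
promoter regions the patient blocks came from; (c) substitutions follow one
of three models: **uniform** (any position, any alternative base),
**signature** (a supplied k-mer mutation signature, COSMIC-style
trinucleotide rows accepted), or **tumor_derived** (the cohort's own
empirical context/alt frequencies, default trinucleotide contexts, `k = 1`
supported).  Signature placement samples a (context, alt) pair from the
signature and then a uniformly chosen matching, not-yet-mutated position of
the current sequence — the signature specifies no separate positional law,
so position eligibility by context is the natural reading.  Contexts are
used as observed, without pyrimidine-strand collapsing, keeping estimation
and placement consistent.

Per TF, the patients' aggregated $\delta$dbA values are compared with the
background alternates' values by the two-sided Wilcoxon rank-sum test
(exact enumeration when both sides have at most 12 untied values, normal
approximation with tie and continuity correction otherwise), and p-values
are Bonferroni-corrected over the number of TFs tested.  Bonferroni is
deliberate: p-values of similar PSAMs are strongly dependent, which breaks
the independence assumptions of FDR procedures, while Bonferroni assumes
nothing.  A patient side smaller than 10 triggers a warning, not an error —
the rank-sum test simply cannot reach significance from very few samples,
however large the effect.

The default significance threshold is corrected $p < 0.001$, the stringent
preset appropriate for larger cohorts; corrected $p < 0.05$ is the
documented preset for small cohorts.  Effect sizes per (patient, TF) are
the $\log_{10}$ fraction of background values at least as extreme — same
sign, at least the magnitude — with add-one smoothing so the logarithm is
finite: $\log_{10}\!\big((1 + n_{\mathrm{extreme}})/(1 + N)\big)$, zero for
a zero delta; more negative means a larger effect, which maps directly to
color shade in the heatmap (`plot_effect_heatmap`, orange = creation,
blue = destruction).

`background_saturation` re-evaluates the significant set using only the
first $n$ background blocks and reports the fraction of the full-background
significant TFs already found, $Y(n)$; the validation experiments show the
curve saturating ($Y \ge 0.9$) by roughly 1000 background blocks, which is
why ~2000 is a comfortable default.

## What the synthetic-data generator emulates

`make_fixture` builds a complete toy dataset from one seed: a random
genome, evenly spaced TSSs (BED6), patient/normal RPKM tables, a PSAM
collection, and somatic mutations with *implanted* ground truth:

* **destroy** effects write a TF's consensus into a promoter and give each
  carrier patient one SNV breaking a consensus base;
* **create** effects write the consensus with a single mismatch and give
  every carrier the same restoring SNV — mimicking the recurrent-position
  hotspots seen in real promoters;
* a **pure-null** preset gives every patient one uniformly placed,
  uniformly substituted SNV in an 80 bp window, so hotspot detection fires
  while the patient mutation process *is* the uniform background process.

Fixture PSAMs are consensus-built (energy $-2$ for the consensus base, 0
otherwise), scaled so occupancy is sensitive within the default $\mu$
ladder; decoy TFs are additional random-consensus PSAMs.  Default cohort
sizes are 12 patients (comfortably above the 10-sample guidance) and 8
normals, with a 4-fold RPKM shift for affected genes and a low background
SNV rate in promoters.

What fixtures do *not* emulate: read-level noise (RPKM is generated
directly), germline variation, indels, linked enhancers, realistic graded
PSAM energies, or genome-scale LD/composition structure.  Passing the
recovery experiments therefore shows the machinery is correct and
calibrated under its stated assumptions, not that real cohorts will yield
comparable effect sizes.

## Validation experiments and the sizes they use

The packaged experiments (also run by `scripts/acceptance.R`) are sized for
a desk-scale reproduction: `recovery_experiment` runs 20 seeded fixtures
(two implanted effects each, 12 carriers) with 200-block backgrounds and
scores an effect as recovered when its block reports the TF significant at
corrected $p < 0.05$ with the right sign; `null_experiment` runs 20
pure-null fixtures; `saturation_experiment` uses one recovery fixture with
a full set of 4000 background blocks.  Recovery runs use the tumor-derived
background model with `k = 1` contexts: a toy cohort observes too few
distinct trinucleotide contexts for context-conditioned placement on
arbitrary short windows, while single-base contexts are always available.

## Numerical and design choices

* **Determinism.**  All shuffle randomness lives in a seeded `mt19937`
  stream inside the scanner; all R-level sampling derives per-unit seeds
  from the master seed via a fixed fold, so identical configurations give
  byte-identical outputs for any worker count, and per-block tasks can be
  distributed (local fork pool or SLURM job arrays) without changing
  results.
* **Exactness.**  Exact rank-sum enumeration for both-sides $\le 12$
  without ties; exact KS where `stats::ks.test` provides it.  The KS null
  is discrete at small sample sizes, so the DE screen's realized type-I
  error sits *below* the nominal $\alpha$ — the tests assert
  conservativeness rather than equality.
* **Ties and degenerate input.**  All-zero delta columns rank
  lexicographically; `d = 0` effect sizes are 0 by convention; empty
  hotspot sets and empty significant sets are valid outputs, not errors.
* **Null calibration.**  The rank-sum null compares the patients'
  *conditional* sample — all patients share one reference sequence — with a
  *marginal* background over many reference windows.  The per-reference
  conditional mean of $\delta$dbA varies from reference to reference, so at
  lenient thresholds (corrected $p < 0.05$) a fraction of pure-null runs
  reports a spurious TF; `null_experiment` measures this directly.  This is
  intrinsic to comparing one shared-reference cohort against
  varied-reference backgrounds and is the practical reason the package
  default is the stringent corrected $p < 0.001$, at which the pure-null
  runs come out clean.  Aggregating the background per block instead of per
  alternate sequence was evaluated and is *worse* (the block means have a
  much tighter spread than patient values, so the two-sided test fires on
  scale differences); the per-alternate background is retained.
* **Known limitations.**  SNV-only; promoter windows only (no enhancers or
  long-range regulation); PSAM inference is out of scope (PSAMs are
  supplied, not learned); the hotspot clustering is a deliberate, simple
  single-linkage rule whose parameters are exposed rather than estimated.

## A minimal run

```{r demo, eval = FALSE}
fx <- make_fixture(fixture_preset("demo", seed = 1), "demo_data")
cfg <- pipeline_config(list(
  genome = fx$genome, mutations = fx$mutations, annotation = fx$annotation,
  expr_patients = fx$expr_patients, expr_normals = fx$expr_normals,
  psam_dir = fx$psam_dir, out_dir = "demo_out",
  background_model = "uniform", n_background = 200,
  sig_alpha = 0.05, seed = 1))
run_pipeline(cfg)
read.table(list.files("demo_out/significance", pattern = "_report",
                      full.names = TRUE)[1], header = TRUE, sep = "\t")
```

The report lists each TF with its raw and corrected p-value, direction, and
mean patient $\delta$dbA; the companion `_effects.tsv` holds the TF-by-
patient effect-size matrix for the heatmap.
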