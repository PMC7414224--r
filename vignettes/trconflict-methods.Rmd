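---
title: "Models and methods behind trconflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trconflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When a replication fork meets the transcription machinery head-on, the
encounter can stall the fork — especially where co-transcriptional
RNA:DNA hybrids (R-loops) persist, as when topoisomerase I activity is
reduced. trconflict implements the desk half of that study design: derive
where forks go from Okazaki-fragment strand counts, decide for every gene
boundary whether replication runs with or against transcription, and
quantify R-loop (DRIP), stalled-fork (p-RPA S33), damage (γ-H2AX) and
break (i-BLESS) signal stratified by that geometry, gene expression,
gene-pair configuration and origin proximity.

# Core models and conventions

## Coordinates

All coordinates are 0-based, half-open (BED convention); anchors are single
base positions: TSS = `start` and TTS = `end − 1` for a `+` gene, mirrored
for `−`. Deterministic orderings break ties by (chromosome order in the
layout, start, end, gene id). BED12 blocks are ignored: every analysis here
operates on gene spans and fixed UTR-proximal windows, never on exon
structure.

## Replication fork direction

Okazaki fragments are synthesized on the lagging strand, so fragments
mapping to the Crick strand mark rightward forks. Per bin,

$$\mathrm{RFD} = \frac{C - W}{C + W} \in [-1, 1],$$

masked (NA) where `C + W < min_coverage` (default 30 fragments/bin at 1 kb
bins). `compute_rfd()` returns the raw ratio by default: at the depths this
package targets the per-bin estimator is already precise
(sd ≈ $\sqrt{1-\mathrm{RFD}^2}/\sqrt{C+W}$ ≈ 0.045 at 500 fragments), and
smoothing before orientation calling would bleed neighboring transition
bins into the anchor bin.

## Initiation zones

`detect_initiation_zones()` scans the smoothed profile for *direct
transits* from ≤ −θ up to ≥ +θ: the zone runs from the last bin at or below
−θ to the first bin at or above +θ, with no return below the start level in
between. This is deliberately looser than strict monotonic ascent, which a
finite-depth estimator violates on almost every real transition; a transit
is the same event up to noise. The efficiency proxy is half the RFD rise
across the zone, so a full −1 → +1 switch scores 1.

**Smoothing window: 5 bins, not 15.** The moving-average window must stay
well below the inter-origin distance. In the default synthetic genome
origins sit ~25–40 kb apart; a 15 kb window smears adjacent ascending
switches together and misses ~20% of efficient origins *on the noiseless
true RFD field*, so the wider window mis-measures the model rather than the
noise. 5 bins (5 kb) keeps ≥ 90% recovery at depth 500 with essentially no
spurious zones. The window is a `conflict_params()` key; raise it for
shallow OK-seq libraries with sparser origins.

## Orientation at anchors

The signed codirectional RFD at an anchor is `s = strand_sign × RFD(anchor
bin)`. Calls use a symmetric threshold θ (default 0.25): `s ≤ −θ` → head-on
(HO), `s ≥ +θ` → codirectional (CD), else ambiguous; masked bins are
ambiguous with a flag. θ = 0.25 corresponds to a 5.5σ margin at 500
fragments/bin — weak bins become ambiguous instead of noisy calls. The
anchor bin alone is used by default (`window_bins = 1`); a window-mean
variant exists for sparse data.

## Peak calling

A bin-level stand-in for MACS2 (model building, tag shifting and sub-bin
summits are intentionally out of scope — the package's contribution is
downstream of peak calling): per bin, `λ = max(genome-wide input mean,
10 kb local input mean) × scale`, p-value = Poisson upper tail, BH across
all bins, q ≤ 0.05 bins merged across ≤ 1-bin gaps, peaks narrower than
2 bins dropped, summit = max-IP bin (leftmost on ties).

**Background scaling is SES-style, not total-count.** Scaling λ by the
IP/input total-count ratio lets the enrichment itself inflate the
background wherever the signal fraction is high — in the dense synthetic
genome the total ratio reaches ~3.4 and a 3×-background bump becomes
undetectable in principle. λ is therefore scaled by the lower-quartile
bin-count ratio, which estimates the library ratio from the least-enriched
bins (the logic of SES background normalization) and reduces to the
total-count ratio under the null. Degenerate quartiles (very low coverage)
fall back to the total ratio.

Replicate filtering keeps a replicate-1 peak when every other replicate
(2–5 supported) matches it at ≥ 50% reciprocal overlap, intersecting the
matched intervals. This replaces IDR: it is monotone, deterministic and
transparent, at the cost of IDR's rank-consistency model.

## Feature annotation

Peak summits are classified with priority TSS region (3 kb upstream through
a 500 bp UTR proxy into the gene) > TTS region (500 bp before the TTS
through 3 kb past it) > gene body > intergenic. Summit-based assignment
keeps the category fractions a partition (they sum to 1). BED6 input has no
UTR annotation, so the fixed 500 bp proxy stands in for the 5′/3′-UTR;
both flanks and the proxy are arguments. The random baseline reported
alongside is the genomic base-pair fraction of each category under the same
priority.

## Expression strata

RPKM = `count × 10⁹ / (length × library size)`; active genes are RPKM > 0.
Quintile 1 holds the most expressed genes; groups 1–4 take `floor(N/5)`
each and the remainder goes to the *lowest*-expression group, so the
printed common size holds exactly (35,251 → 7,050). Expression ties break
lexicographically by gene id for determinism.

## Stratified statistics

TTS windows are ±2 kb (4 kb total; where the source material is ambiguous
between "a 2 kb window" and "±2 kb", the latter is used and the half-width
is an argument). Gap strata for converging pairs split at 5 kb, with
seeded 1,000-resample bootstrap 95% CIs — a CI was chosen because the
stratified means come with no inferential recipe otherwise. Expression
stratification is applied per gene on its own RPKM; for pair-level views
the caller passes member genes. The rank-sum test is the two-sided
normal-approximation Mann–Whitney with tie correction and continuity
correction; it matches `stats::wilcox.test(exact = FALSE, correct = TRUE)`
to 10 significant digits and exhaustive enumeration to within 0.05 at
n ≤ 8, and its type-I error at α = 0.05 calibrates to 0.035–0.065 over
2,000 null draws (both asserted in the suite).

## DSB classification

Per-gene features are the (control, shTop1) i-BLESS TTS scores in
reads-per-million. Clustering is agglomerative, Ward (`ward.D2`) on
Euclidean distances of standardized features, cut at k = 2; the cluster
with the higher mean shTop1 score is DSB+. Both-condition features are the
default (alternatives — shTop1 only, or the difference — are a matter of
passing a different matrix). All-identical features short-circuit to a
degenerate all-DSB− result with a warning. The top-fraction ranking labels
`ceiling(0.25 × N)` genes, ties broken by gene id, flagged degenerate when
every score ties.

# The synthetic world

`sim_config()` states one world; nothing in it is tuned per test:

- **Genome**: one 20 Mb chromosome, 1 kb bins, 2,000 non-overlapping genes
  packed left to right. Gene lengths are log-normal (median 3.5 kb, clamped
  1–15 kb) and gaps a half/half mixture of Unif(0.3, 4.8) kb and
  Unif(5.2, 10) kb, so about half of converging gaps fall below 5 kb.
  Infeasible packing is an explicit error.
- **Strands** follow a Markov chain with switch probability 0.6, giving
  ~30% converging, ~30% divergent, ~40% codirectional adjacent pairs.
- **Expression**: 20% silent; active RPKM log-normal (meanlog 1, sdlog
  1.5) — a heavy right tail like real RNA-seq.
- **Origins**: promoter-proximal with probability 0.7 (top quintile), 0.25
  (other active), 0.05 (silent), placed 0.5–2.5 kb upstream of the TSS,
  plus Poisson intergenic origins (1 per 200 kb); efficiencies
  Unif(0.2, 0.9). Candidates are thinned to ≥ 20 kb spacing keeping the
  most efficient — the fork model needs resolvable origins, and sub-20 kb
  origin pairs are not separable at 1 kb binning in any case.
- **True RFD**: Monte-Carlo over 200 cells; per cell each origin fires
  independently with its efficiency and every bin is replicated by the
  nearest firing origin. This is the simplest generator with realistic RFD
  transitions; promoter origins then make TSS mostly codirectional and TTS
  mostly head-on *emergently*, the geometry the analysis assumes.
- **OK-seq**: per bin total ~ Poisson(depth 500), Crick ~ Binomial(total,
  (1 + RFD)/2).
- **Tracks** (raw Poisson counts/bin): DRIP bumps (σ = 1.5 kb) at TSS and
  TTS of active genes with amplitude 12 × log1p(RPKM) over background 5,
  TTS bumps doubled for converging pairs < 5 kb apart (in both conditions —
  the converging-TTS hotspot is not a depletion phenotype); input is
  background only. p-RPA bumps at TTS gated by max(0, −s): stall signal
  exists only where replication is head-on, proportional to the head-on
  fork fraction. i-BLESS (amplitude 20 over background 2, TTS ± 2 kb) and
  γ-H2AX (flat-top 100 kb domains, amplitude 8 over background 2) appear
  only in the shTop1 condition at DSB+ genes. DSB+ genes are 27% of active
  genes, drawn with weight log1p(RPKM) × (3 if head-on TTS else 0.3) and a
  10% uniform leak so recovery is non-trivial.

**What the generator does not emulate** — and hence what a green test does
not establish: sequence (no FASTA, GC skew, mappability), fragment-length
and cross-correlation structure, replication timing, copy-number or
chromatin-state covariates, multi-replicate variability, and the scale of a
real genome (3 Gb, 35k isoform-collapsed genes). Parameter-recovery results
here say the *estimators are consistent with their own model*, not that the
model is the genome.

# Known limitations

**Signal bleed at close converging pairs.** With σ = 1.5 kb Gaussian
R-loop bumps at every active TTS, the partner bump of a converging pair
separated by less than ~5 kb contributes to a ±2 kb TTS window (~25% of
the partner amplitude at a 2.5 kb gap). The gap-stratified statistic
therefore reports close > far even when no converging-specific effect is
planted: juxtaposition of two independent hotspots is indistinguishable
from a shared one by any window mean. The corresponding null expectation in
the acceptance suite is asserted and *fails by design*; removing the
confound would require amplitude deconvolution with a known point-spread
function, which is outside the window-mean contract of `signal_by_gap()`
(and equally outside what the underlying study design could distinguish).

**Broad domains need smoothing.** `broad_domain_width()` thresholds
bin-level values; over a Poisson background the width distribution is
dominated by single-bin noise unless a moving average (window ≪ expected
domain width) is applied first — hence the `smooth_bins` argument, used at
9 bins for 100 kb γ-H2AX domains in the tests.

**Default-density γ-H2AX domains merge.** At the default DSB+ fraction
(27% of active genes) 100 kb domains tile most of a 20 Mb genome; width
*recovery* is therefore demonstrated at a sparse DSB fraction (2%), while
the default world only supports the coarser assertions (domains exist,
broader than p-RPA, absent in control).

# Pipeline and reproducibility

The pipeline config is JSON (one dialect, machine-writable, no added
dependency); every study constant is a key with its default. All
randomness derives from the single config seed (sub-seeds at fixed offsets
per stage/condition), so two runs with one seed are byte-identical — the
writers format numbers with `%.17g`, which round-trips doubles exactly.
Stage results are cached as `.state/*.rds` under the output directory;
`--resume` reloads finished stages. Subcommands beyond `all` validate the
requested stage name; dependencies are always satisfied from cache or by
recomputation.
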