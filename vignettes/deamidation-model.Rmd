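---
title: "Predicting spontaneous asparagine deamidation from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting spontaneous asparagine deamidation from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngome)
```

## The model

Internal asparagine residues deamidate spontaneously near neutral pH through
a two-step mechanism whose rate-limiting step is the attack of the backbone
amide nitrogen of the *next* residue (the N+1 residue) on the Asn side-chain
carbonyl, forming a cyclic succinimide. Two consequences drive the model:

1. In unstructured peptides the half-time is governed almost entirely by the
   identity of the N+1 residue — Asn-Gly deamidates in about a day, bulky or
   beta-branched N+1 side chains slow the reaction to months or years.
2. In folded proteins, conformational constraints (helix formation, hydrogen
   bonding) restrict the nucleophilic attack and multiply the half-time by a
   *protection factor*, in direct analogy with protection factors in amide
   hydrogen exchange.

The predicted half-time of an internal Asn is

$$ t_{50} = t_{50}(\text{sequence}) \cdot e^{\,w_H H + w_O (1 - D)} $$

where $t_{50}(\text{sequence})$ is the dipeptide-scale intrinsic half-time
looked up by the N+1 residue, $H \in \{0,1\}$ flags predicted alpha helix at
the Asn, and $D \in [0,1]$ is a per-residue intrinsic disorder score
(1 = fully disordered) used as a proxy for local hydrogen-bond formation.
Strand (E) states carry no protection: during model development only helix
and disorder proved useful, so profiles map E and C alike to $H=0$. With
non-negative weights the protection factor
$P = t_{50}/t_{50}(\text{sequence})$ is at least 1, with equality exactly
for a fully disordered coil. The default weights, $w_H = 0.571$ and
$w_O = 2.989$, are the published averages from repeated stratified-split
training on a curated set of 281 experimentally characterized sites; they
can be refit with `grid_train()`.

```{r}
protection_factor(H = 1, D = 0)    # helical, fully ordered
protection_factor(H = 0, D = 1)    # fully disordered coil: unprotected
```

## The intrinsic half-time table

The packaged `halftimes.tsv` holds the model-peptide (pentapeptide series,
pH 7.4, 37&nbsp;°C) deamidation half-times keyed by the N+1 residue, in days.
Two deliberate properties:

* **No proline entry.** Proline's backbone nitrogen is a tertiary amide and
  cannot perform the succinimide-forming attack; rather than invent a value,
  Asn-Pro sites are reported with a missing half-time (and excluded from the
  whole-protein composition). The same policy applies to non-standard N+1
  letters (X, B, Z, ...).
* **Gly must be the minimum.** The loader enforces it as a safeguard against
  transposed or mis-keyed tables.

Every computation takes the table as an explicit argument, so an alternative
compilation (different temperature, buffer, or newer measurements) is a
drop-in replacement.

## Structural tracks

The model is predictor-agnostic: it consumes a per-residue helix flag and
disorder score, however obtained.

* **File ingestion (the fidelity path).** `parse_horizontal_ss()` reads the
  wrapped H/E/C dialect of secondary-structure predictors ('-' is read as
  coil); `parse_disorder_table()` reads the conventional
  index/residue/score output of disorder predictors with strict contiguity,
  range and residue-identity validation (out-of-range scores are errors,
  never clamped). Reproducing server-grade case-study numbers requires this
  path, because published per-protein results depend on the exact predictor
  versions used to generate the tracks.
* **Bundled fallbacks (the zero-dependency path).** `fallback_helix()`
  smooths Chou–Fasman helix propensities over a 7-residue window (cutoff
  1.05, both config-exposed); `fallback_disorder()` computes a
  charge–hydropathy unfoldability index
  $u = 2.785\,\langle\text{hydrophobicity}\rangle - |\langle q\rangle| - 1.151$
  over a 21-residue window — the window scale at which disorder predictors
  assess local interactions — and squashes it logistically so $u = 0$ maps
  to $D = 0.5$. Both are deterministic pure functions of the sequence.
  Windows shrink symmetrically at the termini rather than padding; this
  keeps edge scores defined and deterministic.

Profiles record provenance (`parsed-external` vs `fallback`) and every
report row inherits it, so approximate tracks cannot be mistaken for
predictor output. The fallbacks are coarse: they know nothing about
homologous sequences, which modern alignment-based predictors rely on, so
fallback-based case rankings should be treated as indicative only.

## Derived per-site and per-protein quantities

For each internal Asn (positions $2..L-1$; terminal Asn deamidate through
different chemistry and are excluded) the package reports the seven
attributes of a standard site table: N+1 identity, the positive/negative
call, $t_{50}$ predicted and intrinsic, the protection factor, percent
deamidation after a horizon (default 2 days) under base-2 exponential decay
$100(1 - 2^{-t/t_{50}})$, and whether the Asn sits in an N[^P][ST]
glycosylation sequon. Sequon sites are flagged but still scored — occupancy
cannot be known from sequence — and the flag is surfaced as a warning.

The whole-protein half-time assumes independent first-order site reactions:
the first deamidation event anywhere in the protein is the minimum of
independent exponential clocks, hence
$t_{50}(\text{Protein}) = 1/\sum_i 1/t_{50,i}$. This harmonic composition is
the unique choice consistent with an exponential survival model; it is
unit-tested against a $10^5$-draw first-event simulation.

Classification uses a half-time threshold with ties called positive — the
conservative direction for a degradation-risk screen. `threshold_at_fpr()`
derives the threshold from a labeled ROC curve as the largest threshold
whose false-positive rate does not exceed the target (default 5%), so the
realized FPR never overshoots.

The hypothetical scan (`hypothetical_scan()`) evaluates every internal
position as if it held an Asn, keeping the wild-type tracks and the actual
N+1 residue — a what-if map for point mutations. Because helix and disorder
predictions derive from windows or alignments, a single substitution is
unlikely to change them much, but re-running the mutant sequence is the
definitive check.

## Evaluation machinery

`build_roc()` sweeps every distinct score as a threshold with
smaller-is-positive orientation (fast deamidators are the positives); ties
are grouped, so the trapezoidal AUC equals the Mann–Whitney statistic with
ties counted one half — verified against exhaustive pair counting in the
tests. `compare_auc()` implements the paired DeLong variance estimate for
correlated AUCs; the published comparison of structure-aware versus
sequence-only ranking cites a method without printing its formula, and
DeLong is the standard choice for paired curves. Our implementation is
cross-checked against an independent reference implementation in the test
suite.

`grid_train()` reproduces the training protocol: repeated stratified
splits (default fraction 0.5, the natural choice when none is stated),
exhaustive grid search of the training AUC over $(w_H, w_O)$, ties broken
to the lexicographically smallest pair, averaged selections reported along
with the tally of splits where the fitted model beats sequence-only scoring
on held-out AUC. The AUC inner loop is compiled (Rcpp), because a grid of
$61 \times 61$ weights over tens of splits on $10^3$–$10^4$ sites evaluates
millions of rankings. The default grid is $[0,6]$ at step 0.1 per axis,
config-exposed per axis; finer steps (e.g. 0.01, commensurate with the
three-decimal published weights) are a parameter away but multiply runtime
by 100.

Dataset curation (`curate_records()`) operationalizes the published rules:
experiments kept only at pH 6.5–8.5 ("neutral or slightly basic", made
numeric here and config-overridable) and at most 313 K; natural-source
samples of unknown age dropped; positives require unequivocal deamidation
with conversion ≥ 50% and half-time < 100 days when quantitative data
exist; negatives are tested-and-absent or half-time > 100 days; everything
else is dropped with a per-record disposition, so the dispositions
partition the input. Records with a half-time of exactly 100 days satisfy
neither inequality and are dropped as insufficient rather than forced into
a class.

## The synthetic benchmark and what it shows

`generate_fixture()` emits sequences with exactly one planted internal
Asn-X site each, inside one of three structural contexts — disordered coil
($H=0$, $D \sim U(0.7,1)$), ordered helix ($H=1$, $D \sim U(0,0.3)$),
ordered coil ($H=0$, $D \sim U(0,0.3)$) — with matching tracks, and labels
obtained by thresholding the model's own half-time at a cutoff and flipping
each label with a noise probability (default 5%, echoing the noise level of
curated experimental labels). The N+1 residue is drawn uniformly from the
half-time table (minus Asn, so the planted site stays unique), spanning the
full intrinsic dynamic range.

Two generator constants deserve explanation:

* **Label cutoff, default 800 days.** The cutoff controls where the
  positive/negative boundary falls in each context once protection is
  applied. A cutoff near the experimental 100-day labeling rule puts the
  boundary below the intrinsic half-time ladder inside helical contexts,
  leaving $w_H$ unidentified — labels would carry no information about the
  helix weight at all. At 800 days the boundary crosses the intrinsic
  ladder inside all three context bands, and inside the ordered-coil band
  it falls in the densest region of the ladder (half a dozen residues
  within a few tenths of a log unit), so both weights are sharply
  identifiable from the labels. This is a well-posedness requirement of
  the recovery experiment, not a fit to any expected value.
* **Fixture size for recovery experiments.** With 5% label noise the
  averaged-weight estimator has sampling error that scales as
  $1/\sqrt{n}$; a recovery experiment should be powered so this error is
  small against the grid step. At zero noise, 2000 sites recover the
  planted weights to within 0.01–0.075 of a 0.1-step grid; the noise term
  dominates beyond that. The packaged recovery harness uses
  $1.2\times10^4$ sites, sized so the estimator's standard deviation
  (below ~0.05 on each coordinate) keeps the averaged weights within one
  grid step for the large majority of seeds.

What passing the synthetic benchmark does **not** show: real experimental
labels are not generated by the model's own functional form; real disorder
and helix tracks are correlated with sequence (here they are assigned by
context, independent of the background residues); and real proteins carry
multiple interacting sites, quaternary structure and disulfides that the
model ignores by design. The fixture validates the estimation machinery,
not the biology.

## Proteome-scale analysis

`batch_predict()` maps the predictor over a multi-FASTA set (per-sequence
failures are logged, not fatal) and `turnover_correlation()` regresses
$\log_{10} t_{50}(\text{Protein})$ on $\log_{10}$ experimental half-life,
keeping only records with positive experimental half-lives and usable
predictions, with auditable exclusion counts. Logarithm base is 10; the
correlation is invariant to the base and to the units of either axis.
p-values use the t-transform of Pearson's r, the conventional choice at
proteome-scale n. Binned counts (0.1 log-unit bins) are an optional export
for density visualization only — the statistic is always computed unbinned.

## Numerical and interface choices

* Positions are 1-based throughout, matching standard residue numbering.
* Reported tables round half-times to 3 significant figures for display
  and carry companion `*_exact` columns at full precision; sorting always
  uses full precision.
* Randomized procedures (`stratified_split()`, `grid_train()`,
  `generate_fixture()`) take explicit seeds, restore the caller's RNG
  state, and are bit-reproducible; report and fixture files contain no
  timestamps.
* The command-line layer (`inst/cli/ngome.R`) is a thin wrapper over the
  exported functions with subcommands `predict`, `scan`, `train`,
  `proteome` and `fixture`; exit codes are 0/1/2
  (success/failure/usage).

## Known limitations

Enzymatic deamidation, terminal-Asn deamidation and acidic-pH chemistry are
out of scope (different mechanisms). Glutamine deamidation, the
isoAsp:Asp product ratio, racemization, and temperature/pH extrapolation of
the half-time table are not modeled. Effects of quaternary structure,
disulfides, ligands and other post-translational modifications are not
captured by sequence-derived tracks; predictions for such proteins should
be read as upper bounds on protection fidelity, not site-level certainties.
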