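# ngome

Sequence-based prediction of spontaneous (non-enzymatic) asparagine
deamidation in proteins.

Internal asparagine residues convert spontaneously to aspartate/isoaspartate
through a succinimide intermediate formed by attack of the N+1 backbone
nitrogen on the Asn side-chain carbonyl. The reaction is a molecular clock:
half-times range from about a day (Asn-Gly in a disordered segment) to
years, and matter for protein turnover, aging, and the shelf life of
biologics. The rate is set by two things the sequence can predict — the
identity of the N+1 residue, and how much local structure restrains the
attacking amide. This package models the half-time of each internal Asn as

    t50 = t50(sequence) · exp(wH·H + wO·(1 − D))

where `t50(sequence)` is the intrinsic dipeptide half-time for the Asn/N+1
pair (packaged table, model peptides at pH 7.4, 37 °C), `H ∈ {0,1}` flags
predicted alpha helix at the Asn, `D ∈ [0,1]` is an intrinsic disorder score
(1 = fully disordered), and `wH = 0.571`, `wO = 2.989` are empirical
protection weights. The exponential is the protection factor
`P = t50/t50(sequence) ≥ 1`. Whole-protein half-times compose sites as
independent first-order clocks: `t50(Protein) = 1/Σ(1/t50_i)`.

Beyond per-site prediction the package implements the full surrounding
machinery: parsers for external secondary-structure (H/E/C strings) and
disorder (index/residue/score tables) predictor output plus deterministic
fallback predictors; N[^P][ST] glycosylation-sequon flagging; hypothetical
per-position Asn scans; ROC/AUC evaluation with a paired DeLong test;
the repeated stratified-split grid training that fits the weights; dataset
curation rules for experimental evidence; proteome-scale batch prediction
with turnover correlation; and a seeded synthetic fixture generator.

## Worked example

```r
library(ngome)
p <- predict_protein("MANGSANAKQLVTTTAEDKKNGSR", protein_id = "demo")
p
#> Deamidation prediction for 'demo' (3 internal Asn, tracks: fallback)
#>  position n_plus_1 is_sequon t50_sequence protection t50_ngome pct_at_horizon
#>        21        G      TRUE         1.03       2.06      2.12         47.900
#>         3        G      TRUE         1.03       8.09      8.33         15.300
#>         7        A     FALSE        24.60       8.90    219.00          0.631
#> t50(Protein) = 1.68 days (first deamidation event, independent sites)
```

Reading the table (sorted by predicted half-time): the Asn-Gly site at
position 21 is the fastest, with an intrinsic dipeptide half-time of about a
day slowed only 2-fold by local structure, so roughly 48% of molecules are
deamidated there after the default 2-day horizon. The Asn-Ala site at
position 7 is intrinsically slow and sits in a more ordered region
(protection factor 8.9), pushing its half-time to ~219 days. Both Asn-Gly
sites fall in N[^P][ST] sequons and may be glycosylated — which would
prevent deamidation — so they are flagged. Here the structural tracks come
from the bundled fallback predictors; for predictor-grade results supply
real secondary-structure/disorder output files via `build_profile()` (or
`--ss-file`/`--disorder-file` on the command line).

Other entry points: `hypothetical_scan()` (where would a mutant Asn
deamidate), `batch_predict()` + `turnover_correlation()` (proteome scale),
`grid_train()` (refit the weights on a labeled site table),
`generate_fixture()` (synthetic benchmarks). A thin CLI with subcommands
`predict`, `scan`, `train`, `proteome`, `fixture` ships in
`inst/cli/ngome.R`.

See `vignettes/deamidation-model.Rmd` for the model assumptions, parameter
choices and limitations.

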