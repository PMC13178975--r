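# Packaged example data (synthetic)

`synthetic_exposure.tsv` / `synthetic_outcome.tsv`: one matched pair of
GWAS summary-statistics files generated by `mrsimss::simulate_gwas_pair()`
(1,000 independent variants, exposure heritability 0.5 across a 5% causal
fraction, n_x = n_y = 100,000, 50% sample overlap with exposure-outcome
correlation 0.5, true causal effect 0.3, seed 20260924). Entirely
simulated; no real cohort data. Intended for examples and command-line
smoke tests only.
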