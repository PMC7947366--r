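Reference statistics from the clinical TAO/ivMP cohort study that this
pipeline re-implements (printed summary tables; the underlying patient data
are not public). Values reported as "<0.001" are stored as 0.0009.

reference_roc_table.csv        ROC/Youden cutoff statistics of the 12 T2RT
                               histogram parameters (90 orbits). The
                               self_consistent flag marks rows whose printed
                               Youden index equals sens/100 + spec/100 - 1
                               after rounding to 3 decimals.
reference_univariate_counts.csv  Dichotomised 2x2 counts (rows sum to 90
                               orbits) with row percentages of the
                               responsive class.
reference_logistic_model.csv   Multivariate logistic model on the
                               dichotomised predictors (beta, SE, OR, 95% CI).
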