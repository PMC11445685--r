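name,value
fewer_primary_tkr,11995
fewer_revision_tkr,2423
fewer_tkr_total,14418
tkr_avoidance_pct,19.5
per_person_saving,7970
per_person_qaly_loss,0.43
crossover_years,9
psa_mean_inmb,-4897
psa_ci_lo,-5229
psa_ci_hi,-4564
psa_pct_sw_quadrant,99.2
ceac_pct_at_threshold,18.6
primary_cost_usd,17095
revision_cost_usd,29959
threshold_usd,19475
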