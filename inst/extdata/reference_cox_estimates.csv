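term,hazard_ratio,ci_low,ci_high
age_years,1.082,1.040,1.125
kps_at_least_70,0.546,0.385,0.775
preop_volume_ml,0.999,0.992,1.005
tvtb_cm,2.406,1.206,4.802
biopsy_only,1.242,0.675,2.285
rtv_ml,1.016,1.006,1.027
radiochemo,0.384,0.258,0.573
age_years:tvtb_cm,0.983,0.972,0.994
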