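# Class 1a antiarrhythmics for maintaining sinus rhythm after cardioversion
# of atrial fibrillation; outcome: all-cause mortality. Trial rows carry the
# reported standard errors (provenance "as_reported") with harm direction
# flags per the published conclusion of increased mortality. The
# Lafuente-Lafuente meta-analysis row carries the published odds ratio with
# its 95% confidence interval; its SE is back-calculated on load.
# Codes: Z = zero events (SE incalculable).
study_id,level,outcome,a,b,c,d,estimate,ci_lower,ci_upper,se,direction,code
Byrne-Quinn,1d,all-cause mortality,,,,,,,,2.02,harm,
Hillestad,1d,all-cause mortality,,,,,,,,2.00,harm,
Karlson,1d,all-cause mortality,,,,,,,,1.42,harm,
Lloyd,1d,all-cause mortality,,,,,,,,1.55,harm,
PAFAC,1b,all-cause mortality,,,,,,,,0.78,harm,
Sodermark,1d,all-cause mortality,,,,,,,,0.73,harm,
SOPAT,1b,all-cause mortality,,,,,,,,1.51,harm,
Steinbeck,1d,all-cause mortality,,,,,,,,,,Z
Lafuente-Lafuente,1c,all-cause mortality,,,,,2.39,1.03,5.59,,,
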