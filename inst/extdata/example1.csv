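# Peri-operative beta-blockade versus placebo for major non-cardiac surgery.
# One row per (study, outcome). The published 2x2 counts are not available,
# so cells carry the reported standard errors of the log effect measures
# (provenance "as_reported"). Direction flags encode the published
# conclusions: benefit for non-fatal myocardial infarction; harm for
# all-cause mortality, cardiovascular mortality and non-fatal stroke.
# Codes: Z = zero events (SE incalculable), N = outcome not reported.
study_id,level,outcome,a,b,c,d,estimate,ci_lower,ci_upper,se,direction,code
Bangalore,1a,all-cause mortality,,,,,,,,0.12,harm,
Bangalore,1a,cardiovascular mortality,,,,,,,,0.16,harm,
Bangalore,1a,non-fatal myocardial infarction,,,,,,,,0.10,benefit,
Bangalore,1a,non-fatal stroke,,,,,,,,0.28,harm,
Poise,1b,all-cause mortality,,,,,,,,0.13,harm,
Poise,1b,cardiovascular mortality,,,,,,,,0.17,harm,
Poise,1b,non-fatal myocardial infarction,,,,,,,,0.10,benefit,
Poise,1b,non-fatal stroke,,,,,,,,0.33,harm,
MaVS,1b,all-cause mortality,,,,,,,,1.07,harm,
MaVS,1b,cardiovascular mortality,,,,,,,,,,Z
MaVS,1b,non-fatal myocardial infarction,,,,,,,,,,N
MaVS,1b,non-fatal stroke,,,,,,,,0.66,harm,
Dipom,1b,all-cause mortality,,,,,,,,0.34,harm,
Dipom,1b,cardiovascular mortality,,,,,,,,0.48,harm,
Dipom,1b,non-fatal myocardial infarction,,,,,,,,0.91,benefit,
Dipom,1b,non-fatal stroke,,,,,,,,,,Z
Mangano,1b,all-cause mortality,,,,,,,,0.85,harm,
Mangano,1b,cardiovascular mortality,,,,,,,,1.22,harm,
Mangano,1b,non-fatal myocardial infarction,,,,,,,,1.22,benefit,
Mangano,1b,non-fatal stroke,,,,,,,,1.11,harm,
Bangalore,1c,all-cause mortality,,,,,,,,0.11,harm,
Bangalore,1c,cardiovascular mortality,,,,,,,,0.15,harm,
Bangalore,1c,non-fatal myocardial infarction,,,,,,,,0.09,benefit,
Bangalore,1c,non-fatal stroke,,,,,,,,0.28,harm,
Wetterslev,1c,all-cause mortality,,,,,,,,0.24,harm,
Wetterslev,1c,cardiovascular mortality,,,,,,,,,,N
Wetterslev,1c,non-fatal myocardial infarction,,,,,,,,0.23,benefit,
Wetterslev,1c,non-fatal stroke,,,,,,,,,,N
Poldermans,1d,all-cause mortality,,,,,,,,0.76,harm,
Poldermans,1d,cardiovascular mortality,,,,,,,,0.76,harm,
Poldermans,1d,non-fatal myocardial infarction,,,,,,,,,,Z
Poldermans,1d,non-fatal stroke,,,,,,,,,,N
Lindenauer,2b,all-cause mortality,,,,,,,,0.02,harm,
Lindenauer,2b,cardiovascular mortality,,,,,,,,,,N
Lindenauer,2b,non-fatal myocardial infarction,,,,,,,,,,N
Lindenauer,2b,non-fatal stroke,,,,,,,,,,N
AHA Guidelines,5,all-cause mortality,,,,,,,,,,N
AHA Guidelines,5,cardiovascular mortality,,,,,,,,,,N
AHA Guidelines,5,non-fatal myocardial infarction,,,,,,,,,,N
AHA Guidelines,5,non-fatal stroke,,,,,,,,,,N
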