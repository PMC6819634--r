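# Calibrated preset: misreporting and prevalence parameters chosen by
# calibrate_error_rates() so that the exact consistency-class distribution
# is as close as possible (least squares on percentages) to the published
# six-class distribution, with attrition margins matching the published
# 3/4/5/6-survey proportions. The calibrated (fp, fn) are illustrative
# values implied by the independent per-wave error model, not estimates of
# the source cohort's true error rates.
n: 10000
prev_ever: 0.165
onset_probs: [0.887, 0.0, 0.0226, 0.0226, 0.0226, 0.0226, 0.0226]
fp: 0.016
fn: 0.13
answer_margins:
  three: 0.0681
  four: 0.0857
  five: 0.1258
  six: 0.5216
monotone_mix: 0.7
ineligible_split:
  wave1_only: 0.69
  wave1_plus_one: 0.21
  wave1_missing: 0.10
seed: 20191029
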