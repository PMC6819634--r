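# Error-free preset: identical cohort structure to paper_like but with
# fp = fn = 0, so every observed sequence is truthful and no record can be
# classified inconsistent. Used for null checks of the classifier and the
# cross-sectional bias computation.
n: 10000
prev_ever: 0.165
onset_probs: [0.887, 0.0, 0.0226, 0.0226, 0.0226, 0.0226, 0.0226]
fp: 0.0
fn: 0.0
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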