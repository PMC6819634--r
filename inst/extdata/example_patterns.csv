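pattern,expected_class
YYY,CONSISTENT_IPV
YYYYYY,CONSISTENT_IPV
NYY,CONSISTENT_LATER_IPV
NNY,CONSISTENT_LATER_IPV
NNNNYY,CONSISTENT_LATER_IPV
NNN,CONSISTENT_NEVER_IPV
NNNNNN,CONSISTENT_NEVER_IPV
YNY,MAINLY_IPV
YYN,MAINLY_IPV
YYYNYY,MAINLY_IPV
YNN,MAINLY_NO_IPV
NYN,MAINLY_NO_IPV
YNNNNN,MAINLY_NO_IPV
YNYN,MIXED_IPV
YNNY,MIXED_IPV
YNNNYN,MIXED_IPV
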