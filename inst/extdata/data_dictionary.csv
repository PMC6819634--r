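column,description,codes
id,unique participant identifier,free text
ipv_w1..ipv_w6,answer to the lifetime IPV item at waves 1-6 (1996/2004/2007/2010/2013/2016),Y = yes; N = no; empty = missing
rel_w1..rel_w6,relationship status at each wave,married; defacto; separated; divorced; widowed; single; empty = missing
pstress_w1..pstress_w6,high partner stress (very or extremely stressed) at each wave,TRUE; FALSE; empty = missing
istress_w1..istress_w6,high income stress (impossible or always difficult to manage) at each wave,TRUE; FALSE; empty = missing
area,baseline area of residence (remoteness index),major_city; inner_regional; outer_regional; remote_very_remote; empty = missing
qual,baseline highest completed qualification,lt_year12; year12; trade_cert_diploma; university; empty = missing
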