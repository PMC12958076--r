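timing,framing,index_n,ontime_n,bin_m14_0,bin_0_7,bin_7_28
none,control,637,286,31,118,137
day-14,neutral,409,168,21,73,74
day-14,positive,893,420,63,204,153
day-14,risk,985,438,69,202,167
day-14,social,483,209,37,95,77
day0,neutral,380,153,16,68,69
day0,positive,560,246,36,108,102
day0,risk,905,400,61,168,171
day0,social,984,468,68,198,202
day+7,neutral,898,389,59,132,198
day+7,positive,878,409,59,149,201
day+7,risk,811,363,43,142,178
day+7,social,1110,489,73,185,231
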