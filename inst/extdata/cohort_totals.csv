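quantity,value
patients_total,654
patients_lnm_positive,291
nodes_resected_total,18609
nodes_positive_total,2015
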