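quantity,value,units
total_nh3,58671,Gg a-1
agricultural_nh3,52325,Gg a-1
trade_related_agricultural_nh3,11840,Gg a-1
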