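sequence=VVTYTTLISGLGKAGRLEEALELFEEMKEKGIVPD
variable_positions=5,35
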