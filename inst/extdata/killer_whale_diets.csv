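species,prey,prey_tp,proportion
killer_whale_fe,salmon,3.3,1.0
killer_whale_mme,higher_vertebrates,4.0,1.0
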