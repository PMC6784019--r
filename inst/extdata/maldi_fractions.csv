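fraction_id,neutral_mass
F21a,3399.41
F21a,3809.61
F21a,3839.61
F22,3809.61
F22,3839.61
F25,3810.60
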