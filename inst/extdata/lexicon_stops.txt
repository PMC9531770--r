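# Chemical surfaces that are real substances but never treatments of
# interest; matched spans are consumed and discarded.
ethanol
water
oxygen
sugar
nicotine
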