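{"frequency_hz":50,"sigma_eta2":4}
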