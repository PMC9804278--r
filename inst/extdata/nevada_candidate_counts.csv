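predictor,n_candidates
summer_precip,240
autumn_precip,222
winter_tmin,227
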