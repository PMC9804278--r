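parameter_class,variable,estimate,ci_half_width
distance,dist,-0.106,0.016
at_site,hli,-0.312,0.127
at_site,cti,-0.038,0.039
between_site,stemp,0.751,0.272
between_site,cti,0.008,0.003
between_site,fprecip,-0.263,0.111
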