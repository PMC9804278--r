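hypothesis,at_site,between_site,n_params,aicc,bic,log_lik,delta_aicc,converged
Global,all uncorrelated at-site,all uncorrelated between-site,14,-261.59,-203.29,147.80,-1.37,FALSE
Temperature + Moisture,"cti, hli","fprecip, cti, stemp",6,-260.22,-229.35,139.11,0.00,TRUE
Temperature,hli,stemp,3,-253.21,-232.63,132.60,7.01,TRUE
Moisture,cti,"fprecip, cti",4,-251.19,-227.18,132.59,9.03,TRUE
Topography,rsp,"srr3, srr27",4,-222.59,-198.58,118.29,37.63,TRUE
Water connectivity,"wetland_betweenness, wetland_centrality",d_stream,4,-222.15,-201.57,117.07,38.07,TRUE
Productivity,"hli, p_wetland",,3,-220.88,-200.30,116.44,39.34,TRUE
Null (distance only),,,1,-220.04,-206.32,114.02,40.18,TRUE
Wetland,"p_wetland, cti",,3,-218.42,-197.84,115.21,41.80,TRUE
Source populations,"ralu_betweenness, ralu_centrality, ralu_degree",d_occupied,5,-215.65,-191.65,114.83,44.57,TRUE
Anthropogenic,,p_impervious,2,-215.39,-195.39,112.29,44.83,TRUE
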