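site,mu,n_loci,n_ind,ne_corrected,ci_lo,ci_hi
MERL,Bruneau,10000,12,22.7,9.2,inf
MERU,Bruneau,10000,12,25.0,15.1,55.7
TEGU,Bruneau,10000,12,42.4,17.2,inf
COCA,Owyhee,10000,12,28.8,9.4,inf
RICR,Owyhee,10000,12,55.2,27.4,547.3
TRCR,Owyhee,10000,12,26.1,10.3,inf
WCSP,Owyhee,10000,12,66.7,34.7,406.6
DOGE,South Fork Owyhee,10000,12,84.7,32.5,inf
WICR,South Fork Owyhee,10000,12,20.6,7.5,inf
CACR,Salmon Falls,4860,12,8.2,2.6,43.8
DRCR,Salmon Falls,2718,12,17.2,8.5,61.5
CUCR,Marys,6229,12,14.9,4.9,inf
HACR,Marys,5848,12,36.5,20.8,106.6
EFBE,North Fork,10000,14,15.3,9.2,30.8
MACR,North Fork,10000,12,13.1,4.3,150.7
NFHU,North Fork,10000,12,22.9,8.0,inf
TACA,Independence,9122,12,83.2,38.2,inf
COSP,Maggie,3257,12,11.5,4.6,46.0
UMAG,Maggie,4487,11,58.9,19.6,inf
WILL,Willow,4495,12,9.0,3.3,23.4
WILU,Willow,4550,11,32.9,15.7,309.1
GRMO,Ruby,3190,12,17.1,6.6,270.1
PEAL,Ruby,1996,12,14.4,5.3,173.9
ARDO,Reese,771,12,49.0,25.1,304.3
CLCR,Reese,1057,12,10.0,5.7,19.6
INVA,Reese,814,12,12.7,6.0,39.4
WARN,Reese,675,12,44.7,16.4,inf
FAPO,Big Smoky,698,12,3.0,2.1,11.6
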