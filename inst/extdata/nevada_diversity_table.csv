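site,mu,private_alleles,ho,he,pi
MERL,Bruneau,1,0.219,0.216,0.0013
MERU,Bruneau,3,0.216,0.200,0.0012
TEGU,Bruneau,1,0.267,0.271,0.0016
COCA,Owyhee,0,0.244,0.241,0.0014
RICR,Owyhee,0,0.243,0.240,0.0014
RITI,Owyhee,0,0.302,0.284,0.0017
TRCR,Owyhee,2,0.300,0.282,0.0016
WCSP,Owyhee,0,0.244,0.237,0.0014
DOGE,South Fork Owyhee,7,0.191,0.189,0.0011
WICR,South Fork Owyhee,4,0.283,0.265,0.0015
CACR,Salmon Falls,10,0.045,0.043,0.0003
DRCR,Salmon Falls,4,0.030,0.027,0.0002
POCR,Salmon Falls,0,0.040,0.036,0.0002
SFJA,Salmon Falls,0,0.037,0.033,0.0002
CUCR,Marys,13,0.050,0.049,0.0003
HACR,Marys,11,0.060,0.056,0.0003
EFBE,North Fork,34,0.145,0.135,0.0008
MACR,North Fork,8,0.196,0.181,0.0010
NFHU,North Fork,1,0.248,0.245,0.0014
TACA,Independence,13,0.086,0.083,0.0005
COSP,Maggie,31,0.048,0.044,0.0003
UMAG,Maggie,21,0.054,0.053,0.0003
WILL,Willow,3,0.064,0.059,0.0003
WILU,Willow,1,0.065,0.062,0.0004
GRMO,Ruby,56,0.028,0.027,0.0002
PEAL,Ruby,51,0.021,0.021,0.0001
ARDO,Reese,0,0.006,0.005,0.00003
CLCR,Reese,3,0.006,0.006,0.00003
INVA,Reese,0,0.006,0.005,0.00003
WARN,Reese,0,0.005,0.004,0.00003
FAPO,Big Smoky,0,0.005,0.005,0.00003
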