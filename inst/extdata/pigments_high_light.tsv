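pigment	quantity	bin_nm	value
chla	absorption_m2_per_g	400	5.48574859310052
chlc	absorption_m2_per_g	400	0.344829093068324
fucox	absorption_m2_per_g	400	3.06386015003675
diadino	absorption_m2_per_g	400	2.29794234017596
bcar	absorption_m2_per_g	400	1.35335283236613
chla	absorption_m2_per_g	420	18.8539316115761
chlc	absorption_m2_per_g	420	5.31040781113997
fucox	absorption_m2_per_g	420	7.64494833608538
diadino	absorption_m2_per_g	420	7.93817586779249
bcar	absorption_m2_per_g	420	4.86752255959972
chla	absorption_m2_per_g	440	18.8539316115761
chlc	absorption_m2_per_g	440	17.1422063981132
fucox	absorption_m2_per_g	440	12.7048664592473
diadino	absorption_m2_per_g	440	12
bcar	absorption_m2_per_g	440	9.23116346386636
chla	absorption_m2_per_g	460	5.48574859310052
chlc	absorption_m2_per_g	460	11.5989970468535
fucox	absorption_m2_per_g	460	14.9559915128594
diadino	absorption_m2_per_g	460	7.93817586779249
bcar	absorption_m2_per_g	460	9.23116346386636
chla	absorption_m2_per_g	480	0.464412441980763
chlc	absorption_m2_per_g	480	1.64508759640885
fucox	absorption_m2_per_g	480	14.2040611586036
diadino	absorption_m2_per_g	480	2.29794234017596
bcar	absorption_m2_per_g	480	4.86752255959972
chla	absorption_m2_per_g	500	0.0114394663516288
chlc	absorption_m2_per_g	500	0.0489071651278245
fucox	absorption_m2_per_g	500	12.5922809181823
diadino	absorption_m2_per_g	500	0.291096161451387
bcar	absorption_m2_per_g	500	1.35335283236613
chla	absorption_m2_per_g	520	8.19863697857308e-05
chlc	absorption_m2_per_g	520	0.000304769023850529
fucox	absorption_m2_per_g	520	10.3887967562531
diadino	absorption_m2_per_g	520	0.0161366273828509
bcar	absorption_m2_per_g	520	0.198410947443703
chla	absorption_m2_per_g	540	1.70966697246151e-07
chlc	absorption_m2_per_g	540	3.98194397534588e-07
fucox	absorption_m2_per_g	540	7.05900120051089
diadino	absorption_m2_per_g	540	0.000391442524159935
bcar	absorption_m2_per_g	540	0.0153381067932446
chla	absorption_m2_per_g	560	1.1349572166138e-10
chlc	absorption_m2_per_g	560	3.40363927694998e-06
fucox	absorption_m2_per_g	560	3.61892420591615
diadino	absorption_m2_per_g	560	4.1552980139084e-06
bcar	absorption_m2_per_g	560	0.000625215037748202
chla	absorption_m2_per_g	580	1.58338037565084e-07
chlc	absorption_m2_per_g	580	0.00707061045548666
fucox	absorption_m2_per_g	580	1.35435661253288
diadino	absorption_m2_per_g	580	1.9302576847962e-08
bcar	absorption_m2_per_g	580	1.34381227763152e-05
chla	absorption_m2_per_g	600	0.000333631822030269
chlc	absorption_m2_per_g	600	0.913294080077495
fucox	absorption_m2_per_g	600	0.366625139371845
diadino	absorption_m2_per_g	600	3.92380435142746e-11
bcar	absorption_m2_per_g	600	1.52299797447126e-07
chla	absorption_m2_per_g	620	0.0913344162764697
chlc	absorption_m2_per_g	620	7.33484284585623
fucox	absorption_m2_per_g	620	0.0716349221537615
diadino	absorption_m2_per_g	620	3.49042523118786e-14
bcar	absorption_m2_per_g	620	9.10147076448797e-10
chla	absorption_m2_per_g	640	3.24852474001821
chlc	absorption_m2_per_g	640	3.66266689417291
fucox	absorption_m2_per_g	640	0.0100984657383402
diadino	absorption_m2_per_g	640	1.35871470237095e-17
bcar	absorption_m2_per_g	640	2.8679750088881e-12
chla	absorption_m2_per_g	660	15.0114495315057
chlc	absorption_m2_per_g	660	0.113718329653896
fucox	absorption_m2_per_g	660	0.00102702592096474
diadino	absorption_m2_per_g	660	2.3144998175567e-21
bcar	absorption_m2_per_g	660	4.76530473529909e-15
chla	absorption_m2_per_g	680	9.01246960802646
chlc	absorption_m2_per_g	680	0.00021952801984527
fucox	absorption_m2_per_g	680	7.53525156767745e-05
diadino	absorption_m2_per_g	680	1.72530137131817e-25
bcar	absorption_m2_per_g	680	4.17501005585054e-18
chla	mass_fraction	NA	0.008
chlc	mass_fraction	NA	0.002
fucox	mass_fraction	NA	0.004
diadino	mass_fraction	NA	0.0045
bcar	mass_fraction	NA	0.002
chla	transfer_efficiency	NA	1
chlc	transfer_efficiency	NA	0.95
fucox	transfer_efficiency	NA	0.8
diadino	transfer_efficiency	NA	0.15
bcar	transfer_efficiency	NA	0.2
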