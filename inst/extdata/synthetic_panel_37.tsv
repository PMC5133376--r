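id	risk_allele_freq	or_per_allele
snp01	0.28895779682789	1.03171630048094
snp02	0.384911509673111	1.17089992726506
snp03	0.565568027016707	1.09807922874699
snp04	0.867387010995299	1.19453365374385
snp05	0.23151373793371	1.15259947882589
snp06	0.858550716470927	1.185237934172
snp07	0.900207741744816	1.1305413287084
snp08	0.644718013238162	1.12513682649578
snp09	0.616202639508992	1.18680361637278
snp10	0.105607643420808	1.0139308186304
snp11	0.235377117409371	1.113064824812
snp12	0.208901077276096	1.17297190424815
snp13	0.668320561992005	1.16346883629746
snp14	0.395693346392363	0.89834834541549
snp15	0.742857277998701	1.204459013796
snp16	0.497929317876697	0.905674836474805
snp17	0.69585665743798	1.0611456091991
snp18	0.942715485347435	0.976710165531253
snp19	0.39203166149091	1.02992036889735
snp20	0.749700699187815	1.0768478265975
snp21	0.891234707995318	1.1225764692327
snp22	0.240928269154392	1.15614499737125
snp23	0.63650638947729	1.09707675080756
snp24	0.162999586365186	1.21731632328593
snp25	0.290498601854779	1.07184282241057
snp26	0.397502683289349	1.10891746793025
snp27	0.0620512998430058	1.08042187753662
snp28	0.39414916136302	1.15350239267333
snp29	0.832721761148423	1.06403244399341
snp30	0.356314097018912	1.11336571438568
snp31	0.483872103923932	1.18119598026644
snp32	0.58960924288258	1.02670404712698
snp33	0.494187176343985	0.827843873963468
snp34	0.21759584126994	1.08190575047895
snp35	0.794635986746289	1.19908246454487
snp36	0.651620064373128	1.08359925729163
snp37	0.764815874653868	1.08072839591874
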