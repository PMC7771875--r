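id,sex,age,gene_status,histology,group,initial_radiology,aptw_mean,aptw_max,aptw_min,idh_status,mgmt_status,progression_flag
1,M,63,"IDHwt, MGMT meth",GB grade 4,HGG,HGG,2.37,2.61,2.08,wildtype,methylated,FALSE
2,F,51,"IDHwt, unknown MGMT status",GB grade 4,HGG,HGG,3.43,3.89,2.90,wildtype,unknown,FALSE
3,M,48,"IDHwt, unknown MGMT status",Astrocytoma grade 2,LGG,LGG,1.72,1.98,1.09,wildtype,unknown,FALSE
4,M,57,"IDHwt, unknown MGMT status",GB grade 4,HGG,LGG,2.09,3.00,0.83,wildtype,unknown,FALSE
5,M,43,"IDH mut, MGMT meth",GB grade 4,HGG,HGG,2.30,2.88,1.75,mutant,methylated,FALSE
6,M,72,"IDHwt, MGMT meth",GB grade 4,HGG,MET,2.33,2.77,1.41,wildtype,methylated,FALSE
7,M,52,"IDHwt, unknown MGMT status",GB grade 4,HGG,HGG,0.92,1.48,0.14,wildtype,unknown,FALSE
8,M,30,"IDH mut, unknown MGMT status",GB grade 4,HGG,HGG,5.08,5.83,3.93,mutant,unknown,FALSE
9,M,57,"IDH mut, 1p19q-codeletion, unknown MGMT status",Oligodendroglioma grade 2,LGG,LGG,0.88,1.21,0.41,mutant,unknown,FALSE
10,M,52,"IDH mut, MGMT meth",GB grade 4,HGG,MET,2.25,2.88,1.61,mutant,methylated,FALSE
11,M,55,"IDH status unknown, 1p19q-codeletion, MGMT unknown",Oligodendroglioma grade 2,LGG,LGG,2.20,2.35,1.93,unknown,unknown,FALSE
12,M,53,"IDH mut, unknown MGMT status",Oligoastrocytoma grade 2,LGG,LGG,1.74,2.23,1.36,mutant,unknown,TRUE
13,M,73,"IDHwt, MGMT meth",GB grade 4,HGG,MET,4.24,4.86,2.79,wildtype,methylated,FALSE
14,M,43,"IDH mut, unknown MGMT status",Diffuse astrocytoma grade 2,LGG,LGG,1.68,2.06,1.27,mutant,unknown,FALSE
15,F,53,"IDHwt, GFAP+, MGMT non meth",GB grade 4,HGG,LGG,2.07,3.08,1.25,wildtype,non-methylated,FALSE
16,M,46,"IDH and MGMT status unknown",Oligodendroglioma grade 2,LGG,LGG,2.28,2.86,1.54,unknown,unknown,TRUE
17,M,62,"IDH mut, GFAP+, no 1p19q-codeletion, deletion within 19q, MGMT meth",Diffuse astrocytoma grade 2,LGG,LGG,0.94,2.11,0.02,mutant,methylated,FALSE
18,M,31,"IDH mut, unknown MGMT status",GB grade 4,HGG,LGG,2.98,3.80,2.35,mutant,unknown,FALSE
19,M,63,"IDHwt, MGMT meth",GB grade 4,HGG,HGG,2.16,2.62,1.07,wildtype,methylated,FALSE
20,M,61,"IDHwt, MGMT meth",GB grade 4,HGG,HGG,2.07,2.65,1.65,wildtype,methylated,FALSE
21,F,68,"IDHwt, MGMT meth",GB grade 4,HGG,HGG,2.29,2.98,1.57,wildtype,methylated,FALSE
22,F,71,"IDH status unknown, MGMT meth",GB grade 4,HGG,MET,2.80,3.21,2.28,unknown,methylated,FALSE
23,M,26,"IDHwt, MGMT non meth",GB grade 4,HGG,LGG,2.14,3.12,1.40,wildtype,non-methylated,FALSE
24,M,48,"IDHwt, MGMT non meth",Diffuse Astrocytoma grade 2,LGG,LGG,1.54,1.96,1.34,wildtype,non-methylated,FALSE
25,M,65,"not assessed",Adenocarcinoma - GI origin,MET,MET,2.25,2.77,1.31,unknown,unknown,FALSE
26,M,76,"not assessed",Adenocarcinoma - GI origin,MET,MET,2.72,3.19,2.21,unknown,unknown,FALSE
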