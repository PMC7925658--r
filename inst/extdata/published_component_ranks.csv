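species,condition,gene,genorm_rank,normfinder_rank,bestkeeper_rank,deltact_rank,comprehensive_value,final_rank
G_uralensis,stages,ACT,7,5,4,6,5.38,7
G_uralensis,stages,CAC,1,1,3,1,1.32,1
G_uralensis,stages,CYP,1,3,5,4,2.78,2
G_uralensis,stages,DNAJ,9,9,1,9,5.20,6
G_uralensis,stages,DREB,5,4,11,3,5.07,5
G_uralensis,stages,EF1,13,14,14,13,13.49,14
G_uralensis,stages,RAN,8,7,6,8,7.20,9
G_uralensis,stages,TIF1,14,13,10,14,12.63,13
G_uralensis,stages,TUB,10,10,13,10,10.68,10
G_uralensis,stages,UBC2,12,12,8,12,10.84,11
G_uralensis,stages,ABCC2,4,2,9,2,3.46,3
G_uralensis,stages,COPS3,3,6,2,5,3.66,4
G_uralensis,stages,CS,11,11,12,11,11.24,12
G_uralensis,stages,R3HDM2,6,8,7,7,6.96,8
G_uralensis,tissues,ACT,6,7,10,7,7.36,8
G_uralensis,tissues,CAC,1,1,6,3,2.06,2
G_uralensis,tissues,CYP,9,10,11,10,9.97,13
G_uralensis,tissues,DNAJ,4,4,5,4,4.23,4
G_uralensis,tissues,DREB,7,8,12,6,7.97,9
G_uralensis,tissues,EF1,10,12,14,12,11.92,14
G_uralensis,tissues,RAN,11,6,2,8,5.70,5
G_uralensis,tissues,TIF1,13,13,3,13,9.01,11
G_uralensis,tissues,TUB,3,3,8,2,3.46,3
G_uralensis,tissues,UBC2,12,11,4,11,8.73,10
G_uralensis,tissues,ABCC2,5,5,9,5,5.79,6
G_uralensis,tissues,COPS3,14,14,1,14,7.24,7
G_uralensis,tissues,CS,8,9,13,9,9.58,12
G_uralensis,tissues,R3HDM2,1,2,7,1,1.93,1
G_uralensis,interaction,ACT,8,6,13,7,8.13,11
G_uralensis,interaction,CAC,1,2,5,1,1.78,1
G_uralensis,interaction,CYP,7,10,9,9,8.68,13
G_uralensis,interaction,DNAJ,6,1,6,3,3.22,3
G_uralensis,interaction,DREB,5,4,11,4,5.45,5
G_uralensis,interaction,EF1,14,14,14,14,14.00,14
G_uralensis,interaction,RAN,10,8,4,10,7.52,9
G_uralensis,interaction,TIF1,12,12,3,12,8.49,12
G_uralensis,interaction,TUB,9,7,8,8,7.97,10
G_uralensis,interaction,UBC2,11,11,2,11,7.18,8
G_uralensis,interaction,ABCC2,3,5,10,5,5.23,4
G_uralensis,interaction,COPS3,13,13,1,13,6.85,6
G_uralensis,interaction,CS,4,9,12,6,7.14,7
G_uralensis,interaction,R3HDM2,1,3,7,2,2.55,2
G_inflata,stages,ACT,14,14,14,14,14.00,14
G_inflata,stages,CAC,8,7,11,7,8.10,7
G_inflata,stages,CYP,12,13,7,12,10.70,12
G_inflata,stages,DNAJ,9,8,10,8,8.71,8
G_inflata,stages,DREB,5,4,5,4,4.47,4
G_inflata,stages,EF1,6,6,4,6,5.42,6
G_inflata,stages,RAN,1,1,2,1,1.19,1
G_inflata,stages,TIF1,13,12,12,13,12.49,13
G_inflata,stages,TUB,7,11,9,11,9.34,10
G_inflata,stages,UBC2,11,9,13,10,10.65,11
G_inflata,stages,ABCC2,4,5,6,5,4.95,5
G_inflata,stages,COPS3,1,2,1,2,1.41,2
G_inflata,stages,CS,3,3,3,3,3.00,3
G_inflata,stages,R3HDM2,10,10,8,9,9.21,9
G_inflata,tissues,ACT,4,6,9,6,6.00,8
G_inflata,tissues,CAC,10,9,1,10,5.48,6
G_inflata,tissues,CYP,13,13,14,13,13.24,14
G_inflata,tissues,DNAJ,8,7,3,7,5.86,7
G_inflata,tissues,DREB,1,4,8,4,3.36,3
G_inflata,tissues,EF1,12,12,13,12,12.24,12
G_inflata,tissues,RAN,9,8,5,8,7.33,10
G_inflata,tissues,TIF1,14,14,11,14,13.18,13
G_inflata,tissues,TUB,3,5,10,5,5.23,5
G_inflata,tissues,UBC2,11,11,2,11,7.18,9
G_inflata,tissues,ABCC2,6,2,4,3,3.46,4
G_inflata,tissues,COPS3,5,1,6,1,2.34,1
G_inflata,tissues,CS,7,10,12,9,9.32,11
G_inflata,tissues,R3HDM2,1,3,7,2,2.55,2
G_inflata,interaction,ACT,14,13,14,14,13.74,14
G_inflata,interaction,CAC,5,3,4,3,3.66,4
G_inflata,interaction,CYP,12,12,10,12,11.47,12
G_inflata,interaction,DNAJ,6,5,8,5,5.89,6
G_inflata,interaction,DREB,1,2,3,2,1.86,2
G_inflata,interaction,EF1,10,9,13,9,10.13,10
G_inflata,interaction,RAN,7,7,7,7,7.00,7
G_inflata,interaction,TIF1,13,14,11,13,12.70,13
G_inflata,interaction,TUB,11,11,12,11,11.24,11
G_inflata,interaction,UBC2,9,10,6,10,8.57,9
G_inflata,interaction,ABCC2,1,6,1,6,2.45,3
G_inflata,interaction,COPS3,4,1,2,1,1.68,1
G_inflata,interaction,CS,3,4,5,4,3.94,5
G_inflata,interaction,R3HDM2,8,8,9,8,8.24,8
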