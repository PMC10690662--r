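patient_id,age,sex,mri_status,mri_finding,lobar_localization,histology,follow_up_months,engel_class,seeg,surgery,mri_regions,visual,spm,sipcom
1,17,M,positive,R central FLAIR hyperintensity,R Central,FCD 2A,48,1a,MC + LC + MP + LPr R,Idem,MP + LPr + MC + LC R,MP + LPr + MC + LC R,LPr + LC R,LPr + LC + MP + MC R
2,41,F,positive,R posterior temporal cavernoma + R hippocampal sclerosis,R Temporal,FCD 3A,28,1a,AML + ATL R,Idem,PLT R,AML + ATL R,N,N
3,41,M,negative,Negative,R Temporal,FCD 3A,4,1a,AML + ATL R,Idem,N,N,N,N
4,38,M,positive,Bilateral hippocampal sclerosis,R Temporal,Nonspecific gliosis,10,1a,AML + ATL R,Idem,AML R + AML L,AML + ATL R,AML + ATL R,AML + ATL R
5,33,F,positive,L temporal pole atrophy + L amygdala FLAIR hypersignal,L Temporal,Nonspecific gliosis,2,1a,AML + ATL + OI L,Idem,AML + ATL L,AML + ATL L,ATL L,AML + ATL L
6,29,M,positive,L temporal pole blurring + L temporal pole atrophy,L Temporal,Nonspecific gliosis,24,1a,AML + ATL L,Idem,ATL L,AML + ATL L,N,AML + ATL L
7,33,M,negative,Negative,L Temporal,Nonspecific gliosis,32,1a,AML L + ATL L + ATL R,AML + ATL L,N,AML L,N,N
8,25,M,negative,Negative,R TPO,Normal,35,1a,PLT + LP + TPO R,Idem,N,AML + ATL + PLT R,N,PLT R
9,24,F,positive,R parieto-occipital scar + R hippocampal sclerosis,R Temporal,NA,13,1a,AML + ATL R,Idem,AML + PLT R,AML + ATL + PLT R,AML + ATL + PLT R,AML + ATL + PLT R
10,36,F,negative,Negative,R Temporal,NA,3,1a,AML + ATL + PMT + PLT R,Idem,N,N,ATL + PLT R,ATL + PLT R
11,30,F,positive,Left parietal blurring + L parietal FLAIR signal hyperintensity + L transmantle sign,L Parieto-occipital,NA,4,1a,LP + LO L,Idem,LP + LO L,LP + LO L,N,LP + LO L
12,31,F,negative,Negative,R Temporal,FCD 3A,40,1b,ATL R,Idem,N,ATL R,N,ATL R
13,21,F,positive,L insular FLAIR hypersignal,L Temporal,Normal,12,2b,PLT + ATL + OI L,Idem,OI L,AML + ATL + PLT + OI L,N,N
14,40,F,positive,L hippocampal sclerosis,L Temporal,FCD 1C,38,2b,AML + ATL L,Idem,AML L,AML + ATL L,N,N
15,50,M,positive,L temporal pole FLAIR hypersignal + L Temporal pole atrophy,L Temporal,FCD 3D,7,3a,AML + ATL L,Idem,ATL L,AML + ATL L,ATL L,ATL L
16,30,M,negative,Negative,R Frontal,Normal,31,3a,VLPF + DLPF + LPr + MP R,MP + LPr R,N,N,N,N
17,26,M,positive,R hemispheric atrophy + R amygdala and hippocampus FLAIR hypersignal,R Temporal + TPO,Nonspecific gliosis,17,3a,ATL + PLT + TPO R,Idem,ATL + PLT R,ATL + PLT + OI R,ATL + PLT + OI R,ATL + PLT + OI R
18,26,F,negative,Negative,R Frontal,Nonspecific gliosis,36,3a,VLPF + OI R,Idem,N,VLPF + OI R,N,VLPF R
19,28,M,negative,Negative,R Central,Nonspecific gliosis,3,4b,MC + LC R,Idem,N,MC + LC R,N,N
20,34,M,positive,L temporal pole atrophy,L Temporal,Nonspecific gliosis,25,4b,AML + ATL L,Idem,AML + ATL L,AML + ATL L,N,N
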