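no,name,category,rt_min,formula,cas,monoisotopic_mass,measured_mz,ppm_error,topo1_inhibitor
1,"6-Hydroxy-7,8-dimethoxycoumarin",Coumarin,4.16,C11H10O5,107078-01-3,222.0528,223.0600,-0.4,FALSE
2,Isoscopoletin,Coumarin,4.15,C10H8O4,776-86-3,192.0423,193.0497,0.8,FALSE
3,"6,7-Dimethoxycoumarin",Coumarin,4.37,C11H10O4,120-08-1,206.0579,207.0650,-0.8,FALSE
4,Kaempferol-3-O-rutinoside,Flavone,3.82,C27H30O15,17650-84-9,594.1584,595.1653,-0.8,FALSE
5,Quercetin,Flavone,4.34,C15H10O7,117-39-5,302.0427,303.0498,-0.5,TRUE
6,Luteolin,Flavone,4.53,C15H10O6,491-70-3,286.0477,287.0549,-0.3,TRUE
7,Scutellarein,Flavone,4.53,C15H10O6,529-53-3,286.0477,287.0549,-0.3,FALSE
8,Isorhamnetin,Flavone,4.58,C16H12O7,480-19-3,316.0583,317.0657,0.4,TRUE
9,"5,7,3'-Trihydroxy-6,4',5'-trimethoxyflavone",Flavone,5.91,C18H16O8,78417-26-2,360.0845,361.0919,0.3,FALSE
10,Hydroxygenkwanin,Flavone,6.09,C16H12O6,20243-59-8,300.0634,301.0707,0.1,TRUE
11,Eupatilin,Flavone,6.52,C18H16O7,22368-21-4,344.0896,345.0969,0.0,TRUE
12,Genkwanin,Flavone,7.18,C16H12O5,437-64-9,284.0685,285.0758,0.1,FALSE
13,Irisflorentin,Flavone,7.30,C20H18O8,41743-73-1,386.1002,387.1077,0.8,FALSE
14,Phenylalanine,Organic Acid,2.84,C9H11NO2,63-91-2,165.0790,166.0864,0.9,FALSE
15,8-Epiloganic acid,Organic Acid,3.91,C16H24O10,82509-41-9,376.1369,377.1445,0.7,FALSE
16,Chlorogenic acid,Organic Acid,5.23,C16H18O9,327-97-9,354.0951,355.1022,-0.3,TRUE
17,Linolenic acid,Organic Acid,10.70,C18H30O2,463-40-1,278.2246,279.2319,0.1,FALSE
18,alpha-Asarone,Phenylpropanoid,4.81,C12H16O3,2883-98-9,208.1099,209.1174,1.0,FALSE
19,Salidroside + NH3,Phenyl glycoside,3.45,C14H23NO7,10338-51-9,317.1475,318.1546,-0.4,FALSE
20,Sedanolide,Phenphthalide,7.23,C12H18O2,6415-59-4,194.1307,195.1381,0.8,FALSE
21,Aurantio-obtusin,Anthraquinone,6.01,C17H14O7,67979-25-3,330.0739,331.0809,-0.8,FALSE
22,Ethyl vanillin,Phenol,3.59,C9H10O3,121-32-4,166.0630,167.0703,0.5,FALSE
23,Butylparaben,Phenol,4.88,C11H14O3,94-26-8,194.0943,195.1018,1.0,FALSE
24,6-Shogaol,Phenol,7.68,C17H24O3,555-66-8,276.1725,277.1799,0.4,FALSE
25,Genipin,Terpene,3.84,C11H14O5,6902-77-8,226.0841,227.0915,0.3,FALSE
26,Curcumenol,Terpene,7.10,C15H22O2,19431-84-6,234.1620,235.1692,-0.2,FALSE
27,Linderane,Terpene,8.12,C15H16O4,13476-25-0,260.1049,261.1124,1.0,FALSE
28,Patchouli alcohol (loss H2O),Terpene,8.21,C15H24,5986-55-0,204.1878,205.1950,-0.3,FALSE
29,Anise oil,Volatile oil,4.81,C10H12O,4180-23-8,148.0888,149.0962,0.5,FALSE
30,Vitamin B6,Alkaloid,2.57,C8H11NO3,65-23-6,169.0739,170.0812,0.2,FALSE
31,Nicotinamide,Alkaloid,2.73,C6H6N2O,98-92-0,122.0480,123.0554,0.8,FALSE
32,Cordycepin,Alkaloid,3.20,C10H13N5O3,73-03-0,251.1018,252.1089,-0.9,FALSE
33,Bicuculline,Alkaloid,3.71,C20H17NO6,485-49-4,367.1056,368.1125,-1.0,FALSE
34,Piperine,Alkaloid,4.69,C17H19NO3,94-62-2,285.1365,286.1439,0.4,FALSE
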