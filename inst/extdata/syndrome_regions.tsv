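name	omim	band
1p36_del	607872	1p36
2q37_del	600430	2q37
3q29_del_dup	609425|611936	3q29
Wolf-Hirschhorn	194190	4p16.3
Cri_du_Chat	123450	5p15.2
Sotos	117550	5q35.2q35.3
Williams-Beuren	194050	7q11.23
8p23.1_del		8p23.1
Kleefstra	610253	9q34.3
WAGR_11p13_del	194072	11p13
Potocki-Shaffer	601224	11p11.2
Angelman_Prader-Willi	105830|176270	15q11.2
15q24_del_dup	613406	15q24
16p13.3_del_dup	610543|613458	16p13.3
Miller-Dieker_17p13.3_dup	247200|613215	17p13.3
HNPP_CMT1A	162500|118220	17p12
Smith-Magenis_Potocki-Lupski	182290|610883	17p11.2
17q11.2_del	613675	17q11.2
Koolen-De_Vries	610443	17q21.31
Cat-Eye	115470	22q11
DiGeorge_VCFS_22q11.2_dup	188400|192430|608363	22q11.2
Phelan-McDermid	606232	22q13.33
Pelizaeus-Merzbacher	312080	Xq22.2
Rett_Lubs	312750|300260	Xq28
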