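chr1	564423	6300000	1p36_del	0	.	607872	both
chr2	239499999	243199373	2q37_del	0	.	600430	both
chr3	195720166	197354826	3q29_del_dup	0	.	609425|611936	both
chr4	1499999	2300000	Wolf-Hirschhorn	0	.	194190	both
chr5	10899999	12600000	Cri_du_Chat	0	.	123450	both
chr5	176444999	176830000	Sotos	0	.	117550	both
chr7	72744454	74142672	Williams-Beuren	0	.	194050	both
chr8	8099999	11900000	8p23.1_del	0	.	.	both
chr9	140513443	140730578	Kleefstra	0	.	610253	both
chr11	31799999	32460000	WAGR_11p13_del	0	.	194072	both
chr11	43993999	46052000	Potocki-Shaffer	0	.	601224	both
chr15	23656945	28525460	Angelman_Prader-Willi	0	.	105830|176270	both
chr15	74377173	75567860	15q24_del_dup	0	.	613406	both
chr16	3714999	3930000	16p13.3_del_dup	0	.	610543|613458	both
chr17	524999	2588909	Miller-Dieker_17p13.3_dup	0	.	247200|613215	both
chr17	14097914	15470903	HNPP_CMT1A	0	.	162500|118220	both
chr17	16773071	20222149	Smith-Magenis_Potocki-Lupski	0	.	182290|610883	both
chr17	29107490	30265075	17q11.2_del	0	.	613675	both
chr17	43703800	44164691	Koolen-De_Vries	0	.	610443	both
chr22	16099999	18650000	Cat-Eye	0	.	115470	both
chr22	18877786	21465672	DiGeorge_VCFS_22q11.2_dup	0	.	188400|192430|608363	both
chr22	51113069	51171640	Phelan-McDermid	0	.	606232	both
chrX	102899999	103200000	Pelizaeus-Merzbacher	0	.	312080	both
chrX	153194999	153600000	Rett_Lubs	0	.	312750|300260	both
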