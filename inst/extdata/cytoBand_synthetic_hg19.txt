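chr1	0	13668132	p36.32	gneg
chr1	13668132	125000000	p36.12	gneg
chr1	125000000	249250621	q21.1	gneg
chr2	0	47578338	p21	gneg
chr2	47578338	63202787	p16.3	gneg
chr2	63202787	93300000	p12	gneg
chr2	93300000	159185508	q11.2	gneg
chr2	159185508	221475454	q35	gneg
chr2	221475454	243199373	q36.1	gneg
chr3	0	25269189	p24.3	gneg
chr3	25269189	32723875	p24.1	gneg
chr3	32723875	40114196	p22.3	gneg
chr3	40114196	91000000	p21.31	gneg
chr3	91000000	138522587	q22.2	gneg
chr3	138522587	198022430	q24	gneg
chr4	0	4591029	p16.3	gneg
chr4	4591029	11146663	p16.1	gneg
chr4	11146663	15522284	p15.33	gneg
chr4	15522284	18979989	p15.32	gneg
chr4	18979989	24496188	p15.31	gneg
chr4	24496188	32193616	p15.1	gneg
chr4	32193616	50400000	p14	gneg
chr4	50400000	191154276	q24	gneg
chr5	0	48400000	p11	gneg
chr5	48400000	180915260	q11	gneg
chr6	0	12838175	p25.3	gneg
chr6	12838175	38308556	p22.2	gneg
chr6	38308556	61000000	p12.3	gneg
chr6	61000000	123267615	q21	gneg
chr6	123267615	139286025	q23.2	gneg
chr6	139286025	171115067	q24.2	gneg
chr7	0	59900000	p11	gneg
chr7	59900000	159138663	q11	gneg
chr8	0	45600000	p12	gneg
chr8	45600000	146364022	q23.3	gneg
chr9	0	2307966	p24.3	gneg
chr9	2307966	21463446	p24.2	gneg
chr9	21463446	49000000	p13.1	gneg
chr9	49000000	133902090	q33.3	gneg
chr9	133902090	141213431	q34.3	gneg
chr10	0	40200000	p11	gneg
chr10	40200000	49477693	q11.22	gneg
chr10	49477693	58453555	q11.23	gneg
chr10	58453555	101375866	q21.3	gneg
chr10	101375866	135534747	q26.3	gneg
chr11	0	53700000	p11	gneg
chr11	53700000	107461158	q22.1	gneg
chr11	107461158	125569894	q23.3	gneg
chr11	125569894	135006516	q25	gneg
chr12	0	35800000	p12.1	gneg
chr12	35800000	133851895	q11	gneg
chr13	0	17900000	p11	gneg
chr13	17900000	104776454	q31.3	gneg
chr13	104776454	115169878	q34	gneg
chr14	0	17600000	p11	gneg
chr14	17600000	49658746	q11.2	gneg
chr14	49658746	107349540	q24.3	gneg
chr15	0	19000000	p11	gneg
chr15	19000000	37412683	q11.2	gneg
chr15	37412683	65751344	q21.2	gneg
chr15	65751344	102531392	q25.1	gneg
chr16	0	36600000	p11	gneg
chr16	36600000	90354753	q23.2	gneg
chr17	0	24000000	p11.2	gneg
chr17	24000000	81195210	q11	gneg
chr18	0	17200000	p11	gneg
chr18	17200000	78077248	q11	gneg
chr19	0	13899208	p13.2	gneg
chr19	13899208	26500000	p13.13	gneg
chr19	26500000	59128983	q13.2	gneg
chr20	0	27500000	p11	gneg
chr20	27500000	63025520	q11	gneg
chr21	0	13200000	p11	gneg
chr21	13200000	48129895	q11	gneg
chr22	0	14700000	p11	gneg
chr22	14700000	17996912	q11.1	gneg
chr22	17996912	22714499	q11.21	gneg
chr22	22714499	34808496	q11.23	gneg
chr22	34808496	48377510	q13.31	gneg
chr22	48377510	51304566	q13.33	gneg
chrX	0	4447365	p22.33	gneg
chrX	4447365	12089668	p22.31	gneg
chrX	12089668	19913860	p22.2	gneg
chrX	19913860	33664474	p22.11	gneg
chrX	33664474	51179523	p11.3	gneg
chrX	51179523	60600000	p11.21	gneg
chrX	60600000	155270560	q28	gneg
chrY	0	12500000	p11	gneg
chrY	12500000	59373566	q11	gneg
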