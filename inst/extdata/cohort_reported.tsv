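sample_key	result	referral	case_target
S01	1p36.32p36.12(4,481,264-22,855,001)x1	Nuchal 2.9 mm, cleft lip and palate, adjusted risk for trisomy 21 of 1/361, adjusted risk for trisomies 13 & 18 of 1/53.
S02	1q21.1(145,413,387-145,747,269)x1	Suspected TAR syndrome, absent or shortened radius & ulna bilaterally, bilateral radial aplasia with shortened phalanges and di-phalyngeal thumbs, both hands acutely abducted, both ulnae are approx 2/3 the normal length, humeri on the 5th centile, long bones of the lower limbs are on the 50th centile.	RBM8A
S03	3p21.31(45,266,030-48,311,229)x3	Known familial insertion of chr3 material into another chromosome.
S04	3p24.1p22.3(30,485,387-34,962,363)x1	Bilateral borderline ventriculomegaly, absent cavum septum pellucidum.
S05	4p16.3p14(72,446-35,935,983)x1	Nuchal 3.1 mm.
S06	4p16.3p16.1(514,449-8,667,610)x1	Bilateral talipes, cleft lip, single umbilical artery.
S07	4p15.33p15.32(13,625,716-17,418,852)x1	Interuterine growth retardation, low PAPPA and combined tests.
S08	4p15.31p15.1(20,541,127-28,451,250)x1	Nuchal 2.0 mm, exomphalos, absent nasal bone, reverse ductus.
S09	6p25.3p22.2(259,527-25,416,824)amp	Mild ventriculomegaly, potential brain abnormality.
S10	6q23.2q24.2(135,056,331-143,515,719)x1	Oligohydramnios, echogenic bowel.
S11	9p24.3(214,366-2,197,859)x1,9p24.2p13.1(2,418,074-40,508,819)x3	Bilateral genu recurvatum, moderate ventriculomegaly.
S12	9p24.3p13.1(214,366-40,508,819)x4	Nuchal 8.3 mm.
S13	9q33.3q34.3(126,795,265-141,008,915)x3	Muscular ventral-septal defect, tricuspid regurgitation, abnormally shaped aortic arch.
S14	10q11.22q11.23(46,951,236-52,004,151)x1	Bilateral ventriculomegaly.
S15	11q23.3q25(116,693,628-134,446,160)x3, 22q11.1q11.21(16,053,472-20,311,763)x3	Possible micrognathia with prominent upper lip, brain cyst, dilated 3rd ventricle, stomach not clearly insulated, complete or partial agenisis of corpus callosum, deficient cerebellar vermis.
S16	13q31.3q34(94,493,888-115,059,020)x1	High risk for trisomy 13, holoprosencephaly, diaphragmatic hernia, cleft palate
S17	15q21.2q25.1(51,740,270-79,762,418)x3	Shortened femur, bilateral hydronephrosis, interuterine growth retardation, 2x vessel cord, dysmorphic, downslanting palpebral fissures, low set ears.
S18	17p11.2(16,532,735-20,221,695)x3	Long bones around or below 3rd centile (including femur), dilation of the intra-abdominal portion of the umbilical vein (varix).
S19	22q11.1q13.33(17,096,854-51,178,264)x3	Nuchal 4.4 mm, trisomy 21 risk of 1:61.
S20	22q11.21(18,896,971-21,440,514)x1	Nuchal 4.2 mm, trisomy 21 risk of 1:70.
S21	22q11.21(18,896,971-21,801,661)x3	Ventriculomegaly, hydronephrosis, shortening of the long bones.
S22	22q13.31q13.33(45,576,756-51,178,264)x1	Echogenic bowel, urinary tract/renal anomaly.
S23	Xp11.3p11.21(44,307,282-58,051,765)x1∼2	Intrauterine growth retardation, talipes, stomach not visible on ultrasound.
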