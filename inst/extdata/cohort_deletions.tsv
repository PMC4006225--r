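sample_key	result	referral	footnote
D01	1q21.1(145,413,387-145,747,269)x1	Nuchal 4.5 mm.
D02	2p21(44,507,914-44,531,188)x1	Brain ventricle/hemisphere >97th centile, trisomy 21 risk of 1:13.
D03	2p16.3(50,881,995-50,947,729)x1	Complete transposition of the great arteries.
D04	2p12(75,347,691-75,729,632)x1	Tricuspid valve dysplasia, fetal hydrops.
D05	2q35(220,096,681-220,116,241)x1	Nuchal 1.6 mm, absent ductus venous, trisomy 21 risk of 1:19121, trisomy 13/18 risk of 1:35067.
D06	2q36.1(222,834,667-224,926,273)x1	Nuchal 4.1 mm, trisomy 21 risk of 1:112.	PAX3
D07	3p24.3(20,021,595-20,052,991)x1	Nuchal 1.5 mm, echogenic bowel, liver anomaly.
D08	4q24(107,063,807-107,248,637)x1	Isolated aberrant right subclavian artery.
D09	6p22.2(26,440,746-26,463,502)x1	Tetralogy of Fallot, small for gestational age (<10th centile).
D10	8q23.3(113,630,231-113,960,067)x1	Nuchal 4.1 mm.
D11	10q26.3(135,352,371-135,372,492)x1	Nuchal 2.5 mm, trisomy 21 risk of 1:2005, stomach on right side, suspected arterioventricular defect.
D12	11q22.1(97,762,150-98,228,688)x1	Trisomy 21 risk of 1:8.
D13	14q24.3(76,352,571-76,522,811)x1	Nuchal 5 mm.
D14	15q11.2(22,318,596-23,085,096)x1	Severe growth restriction, oligohydramnios.
D15	15q11.2(22,765,627-23,085,096)x1	Aberrant right subclavian artery.
D16	15q11.2(22,765,627-23,085,096)x1	Left-sided diaphragmatic hernia.
D17	16q23.2(81,293,283-81,367,334)x1	Nuchal 5.7 mm, Trisomy 21 risk of 1:204, Trisomy 13/18 risk of 1:129.
D18	19p13.2(7,070,409-7,168,093)x1	Short long bones, know early pregnancy haematoma (sub chorionic bleeding).	shared_fetus
D19	19q13.2(42,263,338-42,289,030)x1	Nuchal 3.2 mm.
D18	22q11.23(23,627,338-24,040,236)x1	Short long bones, know early pregnancy haematoma (sub chorionic bleeding).	shared_fetus
D20	Xp22.33(1,378,590-1,689,610)x1	Borderline ventriculomegaly.
D21	Xp22.33(2,066,580-2,343,577)x1	Nuchal 4.4 mm.
D22	Xp22.11(23,018,416-23,021,667)x1	Nuchal 3.1 mm, abdominal cyst, crown-rump length small for gestational age, trisomy 21 risk of 1:37.
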