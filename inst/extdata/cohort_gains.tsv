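sample_key	result	referral	footnote	reference
G01	2p16.3(50,625,488-51,057,883)x3	Echogenic bowel.		2
G02	2q11.2(98,019,585-98,274,335)x3	Nuchal 1.0 mm, omphalocele.		2
G03	3q22.2(134,204,455-134,204,970)x4	Atrioventricular septal defect, coarctation of aorta.		2
G04	3q24(142,840,204-143,579,847)x3	Nuchal >4 mm.		2
G05	4q24(102,735,053-102,897,983)x3	Polyhydramnios, ventriculomegaly, bilateral talipes, suspected Charcot-Marie-Tooth syndrome.		2
G06	6p12.3(50,153,611-50,519,464)x3	Nuchal 5.2 mm.		2
G07	6q21(105,548,868-107,397,152)x3	Polyhydramnios, pleural effusion, hydronephrosis.		2
G08	6q21(111,067,339-111,478,900)x3	Hypoplastic left heart syndrome, complex congenital heart disease, interstinal malrotation, suspected 22q11.2 deletion syndrome.		2
G09	8p12(33,210,383-33,455,764)x3	Fetal cardiac abnormality.		2
G10	10q21.3(64,902,960-67,399,362)x3	Coarctation of aorta, large ventricular septal defect, suspected 22q11.2 deletion syndrome.		2
G11	12p12.1(21,615,645-21,689,158)x3	Nuchal 2.3 mm, double outlet right ventricle, spontaneous rupture of membranes.		2
G12	14q11.2(22,323,878-22,964,922)x3	Nuchal 4.3 mm, trisomy 21 risk of 1:10.		2
G13	14q11.2(22,669,442-22,964,922)x3	Intrauterine growth retardation.		2
G14	19p13.2-p13.13(13,865,337-13,933,080)x3	Nuchal 3.8 mm.		2
G15	Xp22.33(658,210-1,259,140)x3	Bilateral talipes.		2
G16	Xp22.33(919,416-1,259,140)x3	Nuchal 1.9 mm, cardiac abnormality.	shared_fetus	2
G17	Xp22.33(970,702-2,017,358)x3	Polyhydramnios, trisomy 21 risk of 1:400.		2
G18	Xp22.33(1,217,016-1,378,646)x3	Aberrant right subclavian artery, suspected 22q11.2 deletion syndrome.		2
G19	Xp22.33(1,314,735-1,347,344)x3	Cardiac anomaly, ventriculomegaly.		2
G20	Xp22.33(1,755,741-2,017,358)x3	Hydrops.		2
G21	Xp22.31(6,551,154-8,032,120)x3	Bilateral talipes.		2
G22	Xp22.2(16,147,216-16,809,305)x2	Nuchal 4.7 mm, trisomy 13 risk of 1:82, trisomy 18 risk of 1:59.		1
G16	Xq28(154,133,237-154,560,375)x2	Nuchal 1.9 mm, cardiac abnormality.	shared_fetus	1
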