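spike_id	subgroup	length	conc_mix1	conc_mix2
SYNERCC-0025	A	250	15	3.75
SYNERCC-0050	A	333	30	7.5
SYNERCC-0075	A	416	60	15
SYNERCC-0100	A	499	120	30
SYNERCC-0125	A	582	240	60
SYNERCC-0150	A	665	480	120
SYNERCC-0175	A	748	960	240
SYNERCC-0200	A	831	1920	480
SYNERCC-0225	A	914	3840	960
SYNERCC-0250	A	997	7680	1920
SYNERCC-0275	A	1080	15360	3840
SYNERCC-0300	A	1163	30720	7680
SYNERCC-0325	A	1246	15	3.75
SYNERCC-0350	A	1329	30	7.5
SYNERCC-0375	A	1412	60	15
SYNERCC-0400	A	1495	120	30
SYNERCC-0425	A	1578	240	60
SYNERCC-0450	A	1661	480	120
SYNERCC-0475	A	1744	960	240
SYNERCC-0500	A	1827	1920	480
SYNERCC-0525	A	1910	3840	960
SYNERCC-0550	A	1993	7680	1920
SYNERCC-0575	A	250	15360	3840
SYNERCC-0600	B	333	30720	30720
SYNERCC-0625	B	416	15	15
SYNERCC-0650	B	499	30	30
SYNERCC-0675	B	582	60	60
SYNERCC-0700	B	665	120	120
SYNERCC-0725	B	748	240	240
SYNERCC-0750	B	831	480	480
SYNERCC-0775	B	914	960	960
SYNERCC-0800	B	997	1920	1920
SYNERCC-0825	B	1080	3840	3840
SYNERCC-0850	B	1163	7680	7680
SYNERCC-0875	B	1246	15360	15360
SYNERCC-0900	B	1329	30720	30720
SYNERCC-0925	B	1412	15	15
SYNERCC-0950	B	1495	30	30
SYNERCC-0975	B	1578	60	60
SYNERCC-1000	B	1661	120	120
SYNERCC-1025	B	1744	240	240
SYNERCC-1050	B	1827	480	480
SYNERCC-1075	B	1910	960	960
SYNERCC-1100	B	1993	1920	1920
SYNERCC-1125	B	250	3840	3840
SYNERCC-1150	B	333	7680	7680
SYNERCC-1175	C	416	15360	23040
SYNERCC-1200	C	499	30720	46080
SYNERCC-1225	C	582	15	22.5
SYNERCC-1250	C	665	30	45
SYNERCC-1275	C	748	60	90
SYNERCC-1300	C	831	120	180
SYNERCC-1325	C	914	240	360
SYNERCC-1350	C	997	480	720
SYNERCC-1375	C	1080	960	1440
SYNERCC-1400	C	1163	1920	2880
SYNERCC-1425	C	1246	3840	5760
SYNERCC-1450	C	1329	7680	11520
SYNERCC-1475	C	1412	15360	23040
SYNERCC-1500	C	1495	30720	46080
SYNERCC-1525	C	1578	15	22.5
SYNERCC-1550	C	1661	30	45
SYNERCC-1575	C	1744	60	90
SYNERCC-1600	C	1827	120	180
SYNERCC-1625	C	1910	240	360
SYNERCC-1650	C	1993	480	720
SYNERCC-1675	C	250	960	1440
SYNERCC-1700	C	333	1920	2880
SYNERCC-1725	C	416	3840	5760
SYNERCC-1750	D	499	7680	15360
SYNERCC-1775	D	582	15360	30720
SYNERCC-1800	D	665	30720	61440
SYNERCC-1825	D	748	15	30
SYNERCC-1850	D	831	30	60
SYNERCC-1875	D	914	60	120
SYNERCC-1900	D	997	120	240
SYNERCC-1925	D	1080	240	480
SYNERCC-1950	D	1163	480	960
SYNERCC-1975	D	1246	960	1920
SYNERCC-2000	D	1329	1920	3840
SYNERCC-2025	D	1412	3840	7680
SYNERCC-2050	D	1495	7680	15360
SYNERCC-2075	D	1578	15360	30720
SYNERCC-2100	D	1661	30720	61440
SYNERCC-2125	D	1744	15	30
SYNERCC-2150	D	1827	30	60
SYNERCC-2175	D	1910	60	120
SYNERCC-2200	D	1993	120	240
SYNERCC-2225	D	250	240	480
SYNERCC-2250	D	333	480	960
SYNERCC-2275	D	416	960	1920
SYNERCC-2300	D	499	1920	3840
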