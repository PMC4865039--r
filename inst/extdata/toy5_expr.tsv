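gene	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10	S11	S12	S13	S14	S15	S16	S17	S18	S19	S20	S21	S22	S23	S24	S25	S26	S27	S28	S29	S30
G1	5.16941885587	4.99527273203	6.70256820666	4.93372528971	6.21632124356	4.14423514871	5.76756039796	4.59910940647	3.82989921388	5.65860189607	4.9463742157	4.98335955238	4.24917222679	4.77626181128	5.47926963164	5.64063233414	3.35144197335	4.66723137757	6.33585182435	2.46055888429	4.2148525994	4.97405304402	5.65990522297	5.57763474246	3.94993218393	6.17726160107	4.08307729872	4.45316327025	6.99250318869	5.01075062609
G2	5.33939763214	5.84227470688	5.47613202208	5.88631058582	5.6965281717	4.39717121507	5.53653653292	4.96623736478	3.77523980097	5.85581444476	3.1791561859	5.16869474801	3.79401441032	4.80814156773	6.5745414723	6.415289721	3.40385980496	3.74386502373	6.79167027327	4.03740001424	6.1946394962	3.62023722294	5.1239371962	5.62130959337	4.51495382818	5.71340452195	3.69590194939	4.80997621566	5.01517547433	5.00218880319
G3	6.07088626157	5.17437494631	4.56035146022	6.0721948098	4.19062349456	4.94718025455	6.5386901925	5.50534274024	4.35482069229	4.31188941816	3.41057100142	4.42421331443	4.52244560221	4.08715663239	5.61428395419	6.72471450621	3.41558901095	3.69238075737	6.15256395724	5.44741615278	6.61625126695	4.39188959297	4.99324868138	6.24802399081	5.75345913986	4.44018871571	4.36457337957	5.48998541337	3.22335547947	5.26133518049
G4	4.66969190185	5.37750090256	5.21305752931	5.68937155647	4.87111954451	5.58313825468	7.1243585099	5.69588407401	4.01603570813	5.53968717106	4.03477670743	3.49394614796	4.54542335047	4.44493050671	5.61963575736	5.43232247833	2.11668750879	5.68193915442	5.05610203043	3.28473342664	4.97819886944	5.42840994601	5.51732105605	5.83811507566	4.20481740538	5.02482234952	5.26439678871	6.8347633831	5.03581358418	4.38299932092
G5	6.07174816651	4.45795975499	4.75102976665	4.89150600193	5.22799377219	4.61153260107	5.38218733502	4.65187419574	4.18250819891	5.56688792401	4.42959816533	5.19123771402	4.89557207672	3.85316228174	4.58736865879	5.62100012383	5.49853383723	3.62573157381	7.73476748527	3.47748457593	6.95460846257	3.8737264798	5.37480324761	6.69822404578	5.7042710253	5.4871171671	3.90132794705	3.70826949921	4.65503625953	4.93293165638
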