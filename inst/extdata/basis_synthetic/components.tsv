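wavelength_nm	helix	strand	coil
200	36868.49	39059.3	-56712.2
200.5	32738.31	37400.4	-55624.39
201	28492.19	35550.23	-54333.54
201.5	24165.93	33526.67	-52853.38
202	19797.59	31348.97	-51199.56
202.5	15426.96	29037.25	-49389.25
203	11094.94	26612.22	-47440.93
203.5	6842.78	24094.7	-45374.03
204	2711.19	21505.37	-43208.58
204.5	-1260.64	18864.41	-40964.91
205	-5036.05	16191.29	-38663.33
205.5	-8581.94	13504.53	-36323.81
206	-11869.81	10821.6	-33965.72
206.5	-14876.61	8158.81	-31607.53
207	-17585.51	5531.23	-29266.64
207.5	-19986.51	2952.74	-26959.15
208	-22076.73	436.01	-24699.72
208.5	-23860.48	-2007.41	-22501.45
209	-25349.07	-4367.02	-20375.81
209.5	-26560.34	-6633.32	-18332.56
210	-27517.88	-8797.66	-16379.8
210.5	-28250.05	-10852.18	-14523.95
211	-28788.83	-12789.79	-12769.84
211.5	-29168.5	-14604.02	-11120.72
212	-29424.28	-16289.07	-9578.45
212.5	-29590.91	-17839.75	-8143.53
213	-29701.35	-19251.51	-6815.31
213.5	-29785.56	-20520.43	-5592.05
214	-29869.44	-21643.33	-4471.1
214.5	-29974.05	-22617.78	-3449.06
215	-30115.02	-23442.19	-2521.88
215.5	-30302.18	-24115.84	-1685.01
216	-30539.57	-24639.04	-933.55
216.5	-30825.63	-25013.09	-262.32
217	-31153.56	-25240.41	333.97
217.5	-31512.05	-25324.49	860.7
218	-31885.98	-25270.01	1323.18
218.5	-32257.36	-25082.71	1726.63
219	-32606.32	-24769.45	2076.12
219.5	-32912.03	-24338.07	2376.49
220	-33153.78	-23797.36	2632.35
220.5	-33311.77	-23156.93	2848.02
221	-33368.03	-22427.07	3027.55
221.5	-33307.05	-21618.59	3174.67
222	-33116.39	-20742.7	3292.85
222.5	-32787.03	-19810.83	3385.23
223	-32313.66	-18834.43	3454.67
223.5	-31694.78	-17824.83	3503.77
224	-30932.58	-16793.07	3534.86
224.5	-30032.84	-15749.76	3550.03
225	-29004.56	-14704.91	3551.16
225.5	-27859.6	-13667.86	3539.91
226	-26612.19	-12647.12	3517.77
226.5	-25278.41	-11650.36	3486.04
227	-23875.63	-10684.3	3445.91
227.5	-22421.97	-9754.69	3398.4
228	-20935.78	-8866.33	3344.43
228.5	-19435.1	-8023.03	3284.84
229	-17937.23	-7227.67	3220.35
229.5	-16458.34	-6482.22	3151.61
230	-15013.15	-5787.83	3079.22
230.5	-13614.67	-5144.89	3003.71
231	-12274.05	-4553.06	2925.57
231.5	-11000.44	-4011.43	2845.23
232	-9801.02	-3518.55	2763.1
232.5	-8681	-3072.53	2679.55
233	-7643.7	-2671.15	2594.93
233.5	-6690.7	-2311.91	2509.55
234	-5822.01	-1992.1	2423.72
234.5	-5036.24	-1708.92	2337.7
235	-4330.84	-1459.49	2251.76
235.5	-3702.28	-1240.93	2166.13
236	-3146.28	-1050.43	2081.04
236.5	-2658.01	-885.23	1996.7
237	-2232.27	-742.7	1913.31
237.5	-1863.66	-620.36	1831.03
238	-1546.74	-515.87	1750.04
238.5	-1276.14	-427.08	1670.48
239	-1046.67	-352	1592.49
239.5	-853.4	-288.83	1516.21
240	-691.71	-235.95	1441.73
240.5	-557.35	-191.9	1369.16
241	-446.44	-155.38	1298.58
241.5	-355.49	-125.25	1230.06
242	-281.4	-100.51	1163.68
242.5	-221.43	-80.31	1099.47
243	-173.22	-63.88	1037.48
243.5	-134.7	-50.58	977.74
244	-104.13	-39.88	920.26
244.5	-80.03	-31.3	865.06
245	-61.14	-24.46	812.13
245.5	-46.43	-19.03	761.47
246	-35.06	-14.74	713.06
246.5	-26.31	-11.36	666.87
247	-19.63	-8.72	622.88
247.5	-14.56	-6.67	581.05
248	-10.73	-5.07	541.34
248.5	-7.87	-3.84	503.7
249	-5.73	-2.9	468.08
249.5	-4.15	-2.17	434.43
250	-2.99	-1.63	402.68
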