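gene	pathway	weight
PI3K_T01	PI3K	0.3168
PI3K_T02	PI3K	1.0273
PI3K_T03	PI3K	-0.5898
PI3K_T04	PI3K	1.155
PI3K_T05	PI3K	-0.6353
PI3K_T06	PI3K	0.1668
PI3K_T07	PI3K	-1.5271
PI3K_T08	PI3K	-2.382
PI3K_T09	PI3K	0.1029
PI3K_T10	PI3K	0.9173
PI3K_T11	PI3K	-0.215
PI3K_T12	PI3K	-1.0905
PI3K_T13	PI3K	1.4499
PI3K_T14	PI3K	-0.5695
PI3K_T15	PI3K	-0.5909
PI3K_T16	PI3K	0.3683
PI3K_T17	PI3K	0.146
PI3K_T18	PI3K	-0.9685
PI3K_T19	PI3K	-2.9016
PI3K_T20	PI3K	-0.5781
PI3K_T21	PI3K	3.0196
PI3K_T22	PI3K	-0.5182
PI3K_T23	PI3K	1.1082
PI3K_T24	PI3K	0.8038
PI3K_T25	PI3K	0.772
PI3K_T26	PI3K	0.223
PI3K_T27	PI3K	0.489
PI3K_T28	PI3K	-0.086
PI3K_T29	PI3K	-0.0055
PI3K_T30	PI3K	-0.2034
PI3K_T31	PI3K	-0.4292
PI3K_T32	PI3K	2.0356
PI3K_T33	PI3K	-0.3183
PI3K_T34	PI3K	1.6366
PI3K_T35	PI3K	-0.0292
PI3K_T36	PI3K	1.0841
PI3K_T37	PI3K	2.9077
PI3K_T38	PI3K	0.3066
PI3K_T39	PI3K	0.104
PI3K_T40	PI3K	1.6217
PI3K_T41	PI3K	0.4188
PI3K_T42	PI3K	0.4998
PI3K_T43	PI3K	-0.7981
PI3K_T44	PI3K	0.2839
PI3K_T45	PI3K	-1.3447
PI3K_T46	PI3K	1.4378
PI3K_T47	PI3K	1.3884
PI3K_T48	PI3K	-0.4171
PI3K_T49	PI3K	-0.8076
PI3K_T50	PI3K	0.346
JAKSTAT_T01	JAK-STAT	-0.2279
JAKSTAT_T02	JAK-STAT	0.1398
JAKSTAT_T03	JAK-STAT	1.241
JAKSTAT_T04	JAK-STAT	-0.6119
JAKSTAT_T05	JAK-STAT	2.1785
JAKSTAT_T06	JAK-STAT	-0.7219
JAKSTAT_T07	JAK-STAT	1.3996
JAKSTAT_T08	JAK-STAT	0.9298
JAKSTAT_T09	JAK-STAT	-0.4263
JAKSTAT_T10	JAK-STAT	-0.9368
JAKSTAT_T11	JAK-STAT	0.2878
JAKSTAT_T12	JAK-STAT	-0.8745
JAKSTAT_T13	JAK-STAT	-0.0221
JAKSTAT_T14	JAK-STAT	1.3001
JAKSTAT_T15	JAK-STAT	0.9417
JAKSTAT_T16	JAK-STAT	-0.4912
JAKSTAT_T17	JAK-STAT	1.2542
JAKSTAT_T18	JAK-STAT	0.0351
JAKSTAT_T19	JAK-STAT	-0.8485
JAKSTAT_T20	JAK-STAT	-1.5702
JAKSTAT_T21	JAK-STAT	1.0477
JAKSTAT_T22	JAK-STAT	0.9435
JAKSTAT_T23	JAK-STAT	-0.6548
JAKSTAT_T24	JAK-STAT	-0.2861
JAKSTAT_T25	JAK-STAT	0.5286
JAKSTAT_T26	JAK-STAT	-0.9772
JAKSTAT_T27	JAK-STAT	0.1379
JAKSTAT_T28	JAK-STAT	-2.0977
JAKSTAT_T29	JAK-STAT	1.4105
JAKSTAT_T30	JAK-STAT	0.2588
JAKSTAT_T31	JAK-STAT	1.0029
JAKSTAT_T32	JAK-STAT	-1.4612
JAKSTAT_T33	JAK-STAT	0.2554
JAKSTAT_T34	JAK-STAT	-0.7144
JAKSTAT_T35	JAK-STAT	-0.3227
JAKSTAT_T36	JAK-STAT	-1.0569
JAKSTAT_T37	JAK-STAT	0.4418
JAKSTAT_T38	JAK-STAT	0.1511
JAKSTAT_T39	JAK-STAT	-0.5709
JAKSTAT_T40	JAK-STAT	-1.4807
JAKSTAT_T41	JAK-STAT	2.2659
JAKSTAT_T42	JAK-STAT	0.3033
JAKSTAT_T43	JAK-STAT	1.0284
JAKSTAT_T44	JAK-STAT	-1.2883
JAKSTAT_T45	JAK-STAT	-1.1331
JAKSTAT_T46	JAK-STAT	0.4177
JAKSTAT_T47	JAK-STAT	-0.6351
JAKSTAT_T48	JAK-STAT	-0.0435
JAKSTAT_T49	JAK-STAT	-0.8219
JAKSTAT_T50	JAK-STAT	-0.2037
NFkB_T01	NFkB	0.7397
NFkB_T02	NFkB	1.5145
NFkB_T03	NFkB	-0.2102
NFkB_T04	NFkB	1.5892
NFkB_T05	NFkB	1.3114
NFkB_T06	NFkB	1.2826
NFkB_T07	NFkB	-0.4887
NFkB_T08	NFkB	1.1009
NFkB_T09	NFkB	0.9877
NFkB_T10	NFkB	0.1624
NFkB_T11	NFkB	-0.2652
NFkB_T12	NFkB	-1.4124
NFkB_T13	NFkB	-1.2232
NFkB_T14	NFkB	-0.3619
NFkB_T15	NFkB	0.8588
NFkB_T16	NFkB	0.3393
NFkB_T17	NFkB	0.6137
NFkB_T18	NFkB	-1.0346
NFkB_T19	NFkB	-0.2125
NFkB_T20	NFkB	-0.7275
NFkB_T21	NFkB	-0.5478
NFkB_T22	NFkB	-1.3402
NFkB_T23	NFkB	0.4052
NFkB_T24	NFkB	0.3987
NFkB_T25	NFkB	-1.8583
NFkB_T26	NFkB	0.2232
NFkB_T27	NFkB	2.1861
NFkB_T28	NFkB	-0.2724
NFkB_T29	NFkB	-0.7083
NFkB_T30	NFkB	1.2451
NFkB_T31	NFkB	0.8234
NFkB_T32	NFkB	0.6025
NFkB_T33	NFkB	-0.351
NFkB_T34	NFkB	0.6335
NFkB_T35	NFkB	-0.5618
NFkB_T36	NFkB	1.7164
NFkB_T37	NFkB	0.1625
NFkB_T38	NFkB	0.0505
NFkB_T39	NFkB	-0.1882
NFkB_T40	NFkB	-0.3531
NFkB_T41	NFkB	0.8262
NFkB_T42	NFkB	-0.8615
NFkB_T43	NFkB	1.0054
NFkB_T44	NFkB	1.3704
NFkB_T45	NFkB	-0.8355
NFkB_T46	NFkB	1.7078
NFkB_T47	NFkB	1.4563
NFkB_T48	NFkB	0.8751
NFkB_T49	NFkB	1.355
NFkB_T50	NFkB	-0.5894
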