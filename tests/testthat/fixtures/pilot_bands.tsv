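metric	mean	sd	lo	hi	n_seeds
fd_mean_f0.1	0.06837644959800476	0.01962810722724952	0	0.14688887850700283	8
fd_mean_f0.3	0.1663524950715304	0.022228503499847417	0.07743848107214074	0.2552665090709201	8
fd_mean_f0.5	0.3101597500328824	0.030703508366314483	0.18734571656762444	0.4329737834981403	8
type1_recall	0.96875	0.08838834764831845	0.6151966094067263	1.3223033905932737	8
strong_recovery	0.625	0.0944911182523068	0.2470355269907728	1.0029644730092273	8
decile_min_drop	0.042903020647339765	0.002880707570658846	0.022903020647339765	0.06290302064733977	8
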