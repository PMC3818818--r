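# nfkbcoupler model parameters (calibrated)
tau_traf1_min = 120
tau_nfkb2_min = 90
ikk_act_rate = 2.7052489910257216
ikk_inact_rate = 0.0018617862237910094
txn_max_ikba = 34.557348107149572
txn_max_traf1 = 54200532.249193296
txn_max_p100 = 265.06717717756214
txn_max_canon_reporter = 1
txn_max_tnip1 = 0.5
hill_K_rela = 0.31192777063474908
hill_K_p52 = 2
hill_h = 2
tln_rate_ikba = 2.3430375048084002
tln_rate_traf1 = 9.1660495331821797e-05
tln_rate_p100 = 402.41954292323408
deg_mrna = 0.17807199603717663
deg_ikba = 0.00028655945304772822
deg_traf1 = 2.2014462455432177e-05
deg_p100 = 1.0362605024971239
deg_p52 = 1.391682012083872e-08
nik_synth_rate = 7.2712679187308051
nik_fast_deg = 1
nik_stable_deg = 1.3163167789911489e-05
traf1_nik_bind = 9.421171077634983e-07
proc_rate = 0.0090224339573276077
proc_K = 1345696.1771489051
ikba_rela_assoc = 0.39929780051172686
ikba_deg_by_ikk = 0.087687278995150622
rela_total = 1
basal_txn = 9.9999999999999995e-07
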