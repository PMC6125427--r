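gene_name	probeset_id	fc_mug_vs_bl_pfc_hyp_g	fc_mug_vs_bl_tx_hyp_g
AKNA	AB075848	1.627	1.670
LOC390988	XM_372755	1.655	1.524
L3MBTL2	AL136564	1.414	1.610
TLN1	BC020881	1.330	1.806
VPS29	BC032462	1.334	1.332
EPHA6	AY358738	-1.404	-1.397
FCRLM1	AF329495	-1.336	-1.322
PCYT1B	NM_004845	-1.319	-1.511
LOC643980	XM_928714	-1.386	-1.757
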