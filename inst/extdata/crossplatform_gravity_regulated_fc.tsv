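gene_name	probeset_id	fc_bl_pfc_hyp_g_vs_1g_if	fc_mug_vs_bl_pfc_hyp_g	fc_mug_vs_bl_tx_hyp_g	fc_bl_tx_hyp_g_vs_gc
CAV1	AF172085	2.280	-1.727	1.955	-2.294
SEC14L3	BC069641	1.921	-1.393	1.914	-1.945
LOC646156	XM_933449	1.756	-1.403	2.228	-1.827
LRRN5	NM_006338	1.494	-1.375	1.961	-1.763
BCAM	BC050450	2.084	-1.594	1.673	-1.674
SPATA21	BC022039	1.722	-1.499	1.681	-1.657
ACRBP	NM_032489	1.676	-1.488	1.631	-1.530
FHAD1	XM_934885	1.667	-1.405	1.587	-1.522
RNF43	NM_017763	1.570	-1.480	1.956	-1.409
GPR45	NM_007227	1.653	-1.478	1.438	-1.389
CCDC25	NM_001031708	-1.395	1.318	-1.450	1.303
UVRAG	BC064837	-1.816	1.346	-1.526	1.351
MLSTD1	NM_018099	-1.802	1.319	-1.557	1.372
ATP6V1E1	NM_001039366	-1.789	1.688	-1.528	1.443
RPL4	NM_000968	-1.398	1.305	-1.366	1.453
ALKBH3	NM_139178	-1.966	1.508	-1.447	1.495
SKP2	NM_005983	-2.057	1.454	-1.515	1.497
ANAPC1	BC104902	-1.444	1.318	-1.707	1.524
KLHL12	NM_021633	-1.482	1.302	-1.638	1.530
LOC158345	XM_931828	-1.370	1.399	-1.339	1.543
C6orf120	NM_001029863	-1.531	1.333	-1.644	1.562
LOC643980	XM_928714	1.382	-1.386	-1.757	1.576
PFAAP5	BC010643	-2.302	1.663	-1.951	1.593
MRS2L	BC069009	-1.655	1.301	-1.623	1.618
RABGAP1L	AB019489	-2.690	1.464	-1.663	1.636
CLEC12A	BC063424	-2.134	1.863	-1.659	1.640
COX11	BC005895	-1.698	1.383	-2.020	1.641
RNF146	AK027558	-1.504	1.433	-1.840	1.656
SMC2L1	NM_006444	-1.736	1.448	-1.832	1.670
CACNA2D3	AF516696	-2.237	1.575	-1.457	1.679
SLFN11	BC052586	-1.628	1.382	-1.882	1.681
NUP88	NM_002532	-2.345	1.780	-1.722	1.701
CSTF3	NM_001033506	-2.306	1.691	-1.501	1.730
DKFZP686M0199	XM_932404	-2.119	1.619	-1.655	1.747
NUP205	NM_015135	-1.542	1.349	-1.450	1.757
XRN1	NM_019001	-1.737	1.333	-1.478	1.764
MASA	NM_021204	-1.651	1.394	-1.688	1.807
CCDC52	BC036951	-2.512	1.655	-1.821	1.842
VLDLR	NM_003383	-2.133	1.488	-1.740	1.849
LOC653198	XM_926455	-2.844	1.454	-1.759	1.876
C18orf25	NM_001008239	-1.888	1.361	-1.748	1.889
C11orf57	BC005403	-2.209	1.904	-1.827	1.936
LOC644305	XM_927477	-2.447	1.598	-1.886	1.973
PXMP3	BC005375	-1.856	1.305	-1.804	2.033
ZNF25	NM_145011	-1.713	1.372	-1.795	2.062
HEATR3	NM_017939	-2.295	1.627	-2.083	2.093
C14orf135	NM_022495	-2.186	1.455	-1.932	2.112
SLC35A1	AJ851889	-2.364	1.884	-1.897	2.162
SCYL2	NM_017988	-1.629	1.312	-1.737	2.177
ANKRD49	BC017798	-1.720	1.347	-1.610	2.315
CLPX	AL136922	-2.210	1.729	-1.614	2.400
FLJ20105	NM_001009954	-2.728	1.687	-1.942	2.462
CLK1	NM_001024646	-2.657	2.114	-1.858	2.785
FLJ20152	NM_001034850	-1.808	1.319	-1.906	3.105
CSTF2T	NM_015235	-2.424	1.505	-1.900	3.661
MCM10	NM_018518	-3.352	1.815	-2.109	3.887
ZNF550	BC034810	-2.594	1.597	-3.259	3.934
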