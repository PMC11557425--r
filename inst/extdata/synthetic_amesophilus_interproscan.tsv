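protein_id	accession	start	end
WP_128706406.1_ScaA_like	cd08548	35	175
WP_128706406.1_ScaA_like	cd08548	190	330
WP_128706406.1_ScaA_like	PF00942	345	505
WP_128706406.1_ScaA_like	cd08548	520	660
WP_128706406.1_ScaA_like	cd08548	675	815
WP_128706406.1_ScaA_like	cd08548	830	970
WP_128706406.1_ScaA_like	cd08548	985	1125
WP_128706406.1_ScaA_like	cd08548	1140	1280
WP_128706406.1_ScaA_like	cd08548	1295	1435
WP_128706406.1_ScaA_like	cd08548	1450	1590
WP_128706406.1_ScaA_like	cd14254	1610	1670
WP_128705811.1_ScaF_like	PF00395	20	70
WP_128705811.1_ScaF_like	PF00395	82	132
WP_128705811.1_ScaF_like	PF00395	144	194
WP_128705811.1_ScaF_like	cd08547	231	371
WP_235832675.1_ScaB_like	cd08547	30	170
WP_235832675.1_ScaB_like	cd08547	185	325
WP_235832675.1_ScaB_like	cd08547	340	480
WP_235832675.1_ScaB_like	cd08547	495	635
WP_235832675.1_ScaB_like	PF00395	670	720
WP_235832675.1_ScaB_like	PF00395	732	782
WP_235832675.1_ScaB_like	PF00395	794	844
PROKKA_02165_ScaC_like	cd08547	25	165
PROKKA_02165_ScaC_like	cd08547	180	320
PROKKA_02165_ScaC_like	PF00395	360	410
PROKKA_02165_ScaC_like	PF00395	422	472
WP_069196093.1_ScaD_like	cd08547	30	170
WP_069196093.1_ScaD_like	cd08548	185	325
WP_069196093.1_ScaD_like	PF00395	350	400
WP_069196093.1_ScaD_like	PF00395	412	462
WP_069196093.1_ScaD_like	PF00395	474	524
WP_235832552.1_ScaG_like	cd08548	40	180
WP_235832552.1_ScaG_like	PF01179	220	560
WP_128706311.1_ScaO_like	cd07477	40	330
WP_128706311.1_ScaO_like	PF05406	350	560
WP_128706311.1_ScaO_like	PF00041	580	665
WP_128706311.1_ScaO_like	PF00041	680	765
WP_128706311.1_ScaO_like	PF00041	780	865
WP_128706311.1_ScaO_like	cd08548	890	1030
WP_128706311.1_ScaO_like	cd14256	1045	1105
DocGH_001	cd14256	25	85
DocGH_001	PF00150	110	460
DocGH_002	cd14256	25	85
DocGH_002	PF00759	110	460
DocGH_003	cd14256	25	85
DocGH_003	PF02011	110	460
DocGH_004	cd14256	25	85
DocGH_004	PF01670	110	460
DocGH_005	cd14256	25	85
DocGH_005	PF02015	110	460
DocGH_006	cd14256	25	85
DocGH_006	PF12891	110	460
DocGH_007	cd14256	25	85
DocGH_007	PF00331	110	460
DocGH_008	cd14256	25	85
DocGH_008	PF01270	110	460
DocGH_009	cd14256	25	85
DocGH_009	PF04616	110	460
DocGH_010	cd14256	25	85
DocGH_010	PF03537	110	460
DocGH_011	cd14256	25	85
DocGH_011	PF00150	110	460
DocGH_012	cd14256	25	85
DocGH_012	PF00759	110	460
DocGH_013	cd14256	25	85
DocGH_013	PF02011	110	460
DocGH_014	cd14256	25	85
DocGH_014	PF01670	110	460
DocGH_015	cd14256	25	85
DocGH_015	PF02015	110	460
DocGH_016	cd14256	25	85
DocGH_016	PF12891	110	460
DocGH_017	cd14256	25	85
DocGH_017	PF00331	110	460
DocGH_018	cd14256	25	85
DocGH_018	PF01270	110	460
DocGH_019	cd14256	25	85
DocGH_019	PF04616	110	460
DocGH_020	cd14256	25	85
DocGH_020	PF03537	110	460
DocGH_021	cd14256	25	85
DocGH_021	PF00150	110	460
DocGH_022	cd14256	25	85
DocGH_022	PF00759	110	460
DocGH_023	cd14256	25	85
DocGH_023	PF02011	110	460
DocGH_024	cd14256	25	85
DocGH_024	PF01670	110	460
DocGH_025	cd14256	25	85
DocGH_025	PF02015	110	460
DocGH_026	cd14256	25	85
DocGH_026	PF12891	110	460
DocGH_027	cd14256	25	85
DocGH_027	PF00331	110	460
DocGH_028	cd14256	25	85
DocGH_028	PF01270	110	460
DocGH_029	cd14256	25	85
DocGH_029	PF04616	110	460
DocGH_030	cd14256	25	85
DocGH_030	PF03537	110	460
DocGH_031	cd14256	25	85
DocGH_031	PF00150	110	460
DocGH_032	cd14256	25	85
DocGH_032	PF00759	110	460
DocGH_033	cd14256	25	85
DocGH_033	PF02011	110	460
DocGH_034	cd14256	25	85
DocGH_034	PF01670	110	460
DocGH_035	cd14256	25	85
DocGH_035	PF02015	110	460
DocGH_036	cd14256	25	85
DocGH_036	PF12891	110	460
DocGH_037	cd14256	25	85
DocGH_037	PF00331	110	460
DocGH_038	cd14256	25	85
DocGH_038	PF01270	110	460
DocGH_039	cd14256	25	85
DocGH_039	PF04616	110	460
DocGH_040	cd14256	25	85
DocGH_040	PF03537	110	460
FreeGH_001	PF00150	30	380
FreeGH_002	PF00759	30	380
FreeGH_003	PF02011	30	380
FreeGH_004	PF01670	30	380
FreeGH_005	PF02015	30	380
CBM3SLH_001	PF00942	30	190
CBM3SLH_001	PF00395	220	270
CBM3SLH_002	PF00942	30	190
CBM3SLH_002	PF00395	220	270
CBM3SLH_003	PF00942	30	190
CBM3SLH_003	PF00395	220	270
RsgI_001	RSGI_PROFILE	40	140
RsgI_002	RSGI_PROFILE	40	140
RsgI_003	RSGI_PROFILE	40	140
RsgI_004	RSGI_PROFILE	40	140
RsgI_005	RSGI_PROFILE	40	140
RsgI_006	RSGI_PROFILE	40	140
RsgI_007	RSGI_PROFILE	40	140
RsgI_008	RSGI_PROFILE	40	140
RsgI_009	RSGI_PROFILE	40	140
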