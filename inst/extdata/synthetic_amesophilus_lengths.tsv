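protein_id	length
WP_128706406.1_ScaA_like	1680
WP_128705811.1_ScaF_like	386
WP_235832675.1_ScaB_like	866
PROKKA_02165_ScaC_like	494
WP_069196093.1_ScaD_like	546
WP_235832552.1_ScaG_like	600
WP_128706311.1_ScaO_like	1115
DocGH_001	480
DocGH_002	480
DocGH_003	480
DocGH_004	480
DocGH_005	480
DocGH_006	480
DocGH_007	480
DocGH_008	480
DocGH_009	480
DocGH_010	480
DocGH_011	480
DocGH_012	480
DocGH_013	480
DocGH_014	480
DocGH_015	480
DocGH_016	480
DocGH_017	480
DocGH_018	480
DocGH_019	480
DocGH_020	480
DocGH_021	480
DocGH_022	480
DocGH_023	480
DocGH_024	480
DocGH_025	480
DocGH_026	480
DocGH_027	480
DocGH_028	480
DocGH_029	480
DocGH_030	480
DocGH_031	480
DocGH_032	480
DocGH_033	480
DocGH_034	480
DocGH_035	480
DocGH_036	480
DocGH_037	480
DocGH_038	480
DocGH_039	480
DocGH_040	480
FreeGH_001	400
FreeGH_002	400
FreeGH_003	400
FreeGH_004	400
FreeGH_005	400
CBM3SLH_001	300
CBM3SLH_002	300
CBM3SLH_003	300
RsgI_001	700
RsgI_002	700
RsgI_003	700
RsgI_004	700
RsgI_005	700
RsgI_006	700
RsgI_007	700
RsgI_008	700
RsgI_009	700
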