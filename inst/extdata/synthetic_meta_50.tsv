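sample_id	pet	age	sex
S001	dog	57.4	F
S002	dog	54.3	M
S003	dog	53.1	F
S004	dog	46.7	F
S005	dog	34.6	F
S006	dog	62	F
S007	dog	33.3	M
S008	dog	49.5	M
S009	dog	37.6	F
S010	dog	23.6	M
S011	dog	53.5	M
S012	dog	35.5	F
S013	dog	71.5	M
S014	dog	52.1	M
S015	dog	45.2	F
S016	dog	56	F
S017	dog	57.4	M
S018	dog	35.7	M
S019	dog	58.7	M
S020	dog	61.1	M
S021	dog	54.4	F
S022	dog	60.7	M
S023	dog	61.1	M
S024	nodog	50.3	M
S025	nodog	37.6	M
S026	nodog	64.1	M
S027	nodog	62.3	M
S028	nodog	38.8	F
S029	nodog	44.9	F
S030	nodog	32	M
S031	nodog	54.4	F
S032	nodog	34.7	F
S033	nodog	62	F
S034	nodog	32.3	M
S035	nodog	48.2	F
S036	nodog	34.7	F
S037	nodog	28.6	M
S038	nodog	61.8	M
S039	nodog	40.7	M
S040	nodog	52	F
S041	nodog	21	F
S042	nodog	47.1	F
S043	nodog	53.7	F
S044	nodog	63	F
S045	nodog	67.8	F
S046	nodog	52.2	M
S047	nodog	42.1	F
S048	nodog	42.5	M
S049	nodog	28	F
S050	nodog	25.8	F
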