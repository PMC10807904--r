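sample_id	pet	age	sex
S019	dog	58.7	M
S020	dog	61.1	M
S021	dog	54.4	F
S022	dog	NA	M
S023	dog	61.1	M
S024	nodog	50.3	M
S025	nodog	37.6	M
S026	nodog	64.1	M
S027	nodog	62.3	M
S028	nodog	38.8	F
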