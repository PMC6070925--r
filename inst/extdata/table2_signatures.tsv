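name	signature	label	studied
Op_MAL1/Opp_AG1	FTAGLVGDN	maltase-isomaltase	TRUE
Le_AG1	HTAGMVGDN	maltase-isomaltase	TRUE
ancMALS	FTAGLVGDE	maltase-isomaltase	TRUE
Sc_MAL12/MAL32/MAL62	FTAGLVAED	maltase	TRUE
Sc_IMA1/IMA2	YVGSLMQDE	isomaltase	TRUE
Sc_IMA3/4	YVGSLMRDE	isomaltase	TRUE
Sc_IMA5	FVGSMVGSE	isomaltase	TRUE
Td_AG1	YVGSLMQDE	isomaltase	FALSE
Cf_AG1.2	HTAGLVGDN	maltase-isomaltase	FALSE
Cf_AG1.1	MVCSLVGSQ	isomaltase	FALSE
Ss_MAL6	YTAGLVGNN	maltase-isomaltase	FALSE
Ss_MAL7	FTAGLVGTN	maltase-isomaltase	FALSE
Ss_MAL8	YTAGLVGEN	maltase-isomaltase	FALSE
Ss_MAL9	YTAGMVGEN	maltase-isomaltase	FALSE
Ss_AGL1	YTAGLVGWN	maltase-isomaltase	FALSE
Mg_AG2	YTAGMVGDN	maltase-isomaltase	FALSE
Mg_AG1	CVAALVGEE	isomaltase	FALSE
Ls_AG1	YTVNKLSHE	maltase	FALSE
Ls_AG6	NTVNRLPGR	maltase	FALSE
Ba_AG2	YTVQIGSRN	maltase	TRUE
Ao_MalT	ITVNMLPDD	maltase	TRUE
Ls_AG2	LAINFMADE	maltase	FALSE
Ls_AG4	HAINFMGTE	maltase	FALSE
Ls_AG5	AAINFMADE	maltase	FALSE
Sp_Mal1	YAINMMPDE	maltase	TRUE
Bs_alpha14_glucosidase	IAISHANGA	maltase	TRUE
Ls_AG3	CVINFMPDE	isomaltase	FALSE
Ls_AG7	EVINYMGQE	isomaltase	FALSE
Ls_AG8	-VINFMPDE	isomaltase	FALSE
Dh_AG1	AVINFMPDE	isomaltase	FALSE
Ba_AG1	YVINLMPQE	isomaltase	FALSE
Bt_oligo16_glucosidase	VVINMTPDE	isomaltase	TRUE
An_AgdC	FVINFMPDD	isomaltase	TRUE
Fo_Foagl1	FVINFMPDD	isomaltase	TRUE
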