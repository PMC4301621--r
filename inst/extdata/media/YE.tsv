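# name=YE
id	lower_bound	upper_bound	role
EX_glc	-0.8	1000	override
EX_no3	-1000	1000	override
EX_ala	-0.01	1000	override
EX_arg	-0.01	1000	override
EX_asn	-0.01	1000	override
EX_asp	-0.01	1000	override
EX_cys	-0.01	1000	override
EX_gln	-0.01	1000	override
EX_glu	-0.01	1000	override
EX_gly	-0.01	1000	override
EX_his	-0.01	1000	override
EX_ile	-0.01	1000	override
EX_leu	-0.01	1000	override
EX_lys	-0.01	1000	override
EX_met	-0.01	1000	override
EX_phe	-0.01	1000	override
EX_pro	-0.01	1000	override
EX_ser	-0.01	1000	override
EX_thr	-0.01	1000	override
EX_trp	-0.01	1000	override
EX_tyr	-0.01	1000	override
EX_val	-0.01	1000	override
EX_o2	NA	NA	always_open
EX_co2	NA	NA	always_open
EX_h2o	NA	NA	always_open
EX_h	NA	NA	always_open
EX_pi	NA	NA	always_open
EX_so4	NA	NA	always_open
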