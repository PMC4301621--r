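# name=MG
id	lower_bound	upper_bound	role
EX_glc	-0.8	1000	override
EX_no3	-1000	1000	override
EX_o2	NA	NA	always_open
EX_co2	NA	NA	always_open
EX_h2o	NA	NA	always_open
EX_h	NA	NA	always_open
EX_pi	NA	NA	always_open
EX_so4	NA	NA	always_open
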