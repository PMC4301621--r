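# 14-source carbon utilization screen; each candidate becomes the sole
# carbon source at uptake 1.0 mmol gDW-1 h-1.  Eight sources are named in
# the study (ethanol, xylose, maltose, rhamnose, glycerol, sucrose,
# d-mannose, raffinose); the remaining six slots are configurable.  The
# exchange_id column maps to the bundled synthetic model where a pathway
# exists; "-" marks sources without a synthetic-model counterpart (edit
# for your own model).
source	exchange_id
glucose	EX_glc
glycerol	EX_glyc
ethanol	EX_etoh
acetate	EX_ac
lactate	EX_lac
rhamnose	EX_rha
xylose	-
maltose	-
sucrose	-
d-mannose	-
raffinose	-
configurable_1	-
configurable_2	-
configurable_3	-
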