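variant_id	beta_exposure	se_exposure	beta_outcome	se_outcome
rs1	0.08	0.010	0.040	0.012
rs2	0.05	0.011	0.020	0.010
rs3	0.10	0.009	0.055	0.015
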