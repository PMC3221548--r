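locus	genotype_label	control_frequency	odds_ratio	is_reference
CFH_rs1061170	0_risk_alleles	0.4225	1	TRUE
CFH_rs1061170	1_risk_allele	0.4550	2.1	FALSE
CFH_rs1061170	2_risk_alleles	0.1225	4.2	FALSE
CFH_rs1410996	0_risk_alleles	0.16	1	TRUE
CFH_rs1410996	1_risk_allele	0.48	1.9	FALSE
CFH_rs1410996	2_risk_alleles	0.36	3.6	FALSE
ARMS2_rs10490924	0_risk_alleles	0.64	1	TRUE
ARMS2_rs10490924	1_risk_allele	0.32	2.4	FALSE
ARMS2_rs10490924	2_risk_alleles	0.04	6.0	FALSE
C2_rs9332739	noncarrier	0.90	1	TRUE
C2_rs9332739	carrier	0.10	0.50	FALSE
CFB_rs641153	noncarrier	0.83	1	TRUE
CFB_rs641153	carrier	0.17	0.45	FALSE
C3_rs2230199	0_risk_alleles	0.64	1	TRUE
C3_rs2230199	1_risk_allele	0.32	1.6	FALSE
C3_rs2230199	2_risk_alleles	0.04	2.4	FALSE
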