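sample	gene	method	allele1	allele2
W4052	SLA-2	PCR-SBT	04:01	04:02:01 or 04:02:02
W4052	SLA-2	NGS	04:01	04:02:01 or 04:02:02
W4052	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W4052	SLA-3	NGS	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W4052	SLA-DRB1	PCR-SBT	02:01:01	05:01 or 05:03
W4052	SLA-DRB1	NGS	02:01:01	05:01 or 05:03
W4052	SLA-DQB1	PCR-SBT	02:01 or 02:05	02:01 or 02:05
W4052	SLA-DQB1	NGS	02:01 or 02:05	02:01 or 02:05
W4217	SLA-2	PCR-SBT	16:03	04:02:01 or 04:02:02
W4217	SLA-2	NGS	01:02	04:02:01 or 04:02:02 or 04:05
W4217	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W4217	SLA-3	NGS	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W4217	SLA-DRB1	PCR-SBT	01:01	05:01 or 05:03
W4217	SLA-DRB1	NGS	01:01	01:01
W4217	SLA-DQB1	PCR-SBT	01:01	02:01 or 02:05
W4217	SLA-DQB1	NGS	01:01	02:01 or 02:05
W4223	SLA-2	PCR-SBT	16:03	04:02:01 or 04:02:02
W4223	SLA-2	NGS	01:02	07:04
W4223	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W4223	SLA-3	NGS	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W4223	SLA-DRB1	PCR-SBT	01:01	05:01 or 05:03
W4223	SLA-DRB1	NGS	01:01	05:01 or 05:03
W4223	SLA-DQB1	PCR-SBT	01:01	02:01 or 02:05
W4223	SLA-DQB1	NGS	01:01	02:01 or 02:05
W5161	SLA-2	PCR-SBT	04:01	16:03
W5161	SLA-2	NGS	04:01	04:09
W5161	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W5161	SLA-3	NGS	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W5161	SLA-DRB1	PCR-SBT	01:01	02:01:01
W5161	SLA-DRB1	NGS	01:01	02:01:01
W5161	SLA-DQB1	PCR-SBT	01:01	02:01 or 02:05
W5161	SLA-DQB1	NGS	01:01	02:01 or 02:05
W5162	SLA-2	PCR-SBT	04:01	16:03
W5162	SLA-2	NGS	04:01	04:05
W5162	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W5162	SLA-3	NGS	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W5162	SLA-DRB1	PCR-SBT	01:01	02:01:01
W5162	SLA-DRB1	NGS	01:01	02:01:01
W5162	SLA-DQB1	PCR-SBT	01:01	02:01 or 02:05
W5162	SLA-DQB1	NGS	01:01	02:01 or 02:05
W4235	SLA-2	PCR-SBT	04:02:01 or 04:02:02	04:03
W4235	SLA-2	NGS	04:02:01 or 04:02:02	04:01
W4235	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W4235	SLA-3	NGS	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W4235	SLA-DRB1	PCR-SBT	02:01:01	05:01 or 05:03
W4235	SLA-DRB1	NGS	02:01:01	05:01 or 05:03
W4235	SLA-DQB1	PCR-SBT	02:01 or 02:05	02:01 or 02:05
W4235	SLA-DQB1	NGS	02:01 or 02:05	02:01 or 02:05
W4550	SLA-2	PCR-SBT	04:02:01 or 04:02:02	15:01
W4550	SLA-2	NGS	04:02:01 or 04:02:02	04:02:01 or 04:02:02 or 04:05
W4550	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	03:03
W4550	SLA-3	NGS	04:01:02 or 04:01 or 04:06	03:03
W4550	SLA-DRB1	PCR-SBT	02:01:01	11:01
W4550	SLA-DRB1	NGS	02:01:01	11:01
W4550	SLA-DQB1	PCR-SBT	02:01 or 02:05	05:03
W4550	SLA-DQB1	NGS	02:01 or 02:05	05:03
W4937	SLA-2	PCR-SBT	04:02:01 or 04:02:02	04:02:01 or 04:02:02
W4937	SLA-2	NGS	04:02:01 or 04:02:02	04:02:01 or 04:02:02
W4937	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W4937	SLA-3	NGS	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W4937	SLA-DRB1	PCR-SBT	02:01:01	02:01:01
W4937	SLA-DRB1	NGS	02:01:01	02:01:01
W4937	SLA-DQB1	PCR-SBT	02:01 or 02:05	02:01 or 02:05
W4937	SLA-DQB1	NGS	02:01 or 02:05	02:01 or 02:05
W5226	SLA-2	PCR-SBT	04:02:01 or 04:02:02	16:03
W5226	SLA-2	NGS	04:09	16:03
W5226	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W5226	SLA-3	NGS	04:01:02 or 04:01 or 04:06	05:03:01 or 05:03:02 or 05:04
W5226	SLA-DRB1	PCR-SBT	01:01	02:01:01
W5226	SLA-DRB1	NGS	01:01	02:01:01
W5226	SLA-DQB1	PCR-SBT	01:01	02:01 or 02:05
W5226	SLA-DQB1	NGS	01:01	02:01 or 02:05
W5621	SLA-2	PCR-SBT	04:02:01 or 04:02:02	04:02:01 or 04:02:02
W5621	SLA-2	NGS	04:02:01 or 04:02:02	04:02:01 or 04:02:02
W5621	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W5621	SLA-3	NGS	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W5621	SLA-DRB1	PCR-SBT	02:01:01	02:01:01
W5621	SLA-DRB1	NGS	02:01:01	02:01:01
W5621	SLA-DQB1	PCR-SBT	02:01 or 02:05	02:01 or 02:05
W5621	SLA-DQB1	NGS	02:01 or 02:05	02:01 or 02:05
W5705	SLA-2	PCR-SBT	04:02:01 or 04:02:02	04:02:01 or 04:02:02
W5705	SLA-2	NGS	04:02:01 or 04:02:02	04:02:01 or 04:02:02
W5705	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W5705	SLA-3	NGS	04:01:02 or 04:01 or 04:06	04:01:02 or 04:01 or 04:06
W5705	SLA-DRB1	PCR-SBT	02:01:01	05:01 or 05:03
W5705	SLA-DRB1	NGS	02:01:01	05:01 or 05:03
W5705	SLA-DQB1	PCR-SBT	02:01 or 02:05	02:01 or 02:05
W5705	SLA-DQB1	NGS	02:01 or 02:05	02:01 or 02:05
W5721	SLA-2	PCR-SBT	04:02:01 or 04:02:02	15:01
W5721	SLA-2	NGS	04:02:01 or 04:02:02	04:02:01 or 04:02:02
W5721	SLA-3	PCR-SBT	04:01:02 or 04:01 or 04:06	03:03
W5721	SLA-3	NGS	04:05	04:05
W5721	SLA-DRB1	PCR-SBT	05:01 or 05:03	11:01
W5721	SLA-DRB1	NGS	05:01 or 05:03	05:01 or 05:03
W5721	SLA-DQB1	PCR-SBT	02:01 or 02:05	05:03
W5721	SLA-DQB1	NGS	02:01 or 02:05	05:03
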