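proband_id	hpo_terms	source
F1	HP:9010010;HP:9050001;HP:9090001;HP:9020001;HP:9070002;HP:9040001	postmortem
F2	HP:9020003;HP:9140001;HP:9010006;HP:9130001;HP:9030005	pediatric
F3	HP:9030003;HP:9110001	ultrasound
F5	HP:9020005;HP:9020006;HP:9070003	postmortem
F6	HP:9160001;HP:9020007;HP:9020001	postmortem
F7	HP:9020001;HP:9110001	ultrasound
F8	HP:9030004;HP:9110001	ultrasound
F9	HP:9030004;HP:9010005	postmortem
F10	HP:9100003	pediatric
F11	HP:9110001;HP:9020002	ultrasound
F12	HP:9030001;HP:9110001	ultrasound
F13	HP:9040002;HP:9010008;HP:9010009;HP:9030004;HP:9010005	postmortem
F14	HP:9030001;HP:9030002	ultrasound
F15	HP:9050002;HP:9110001	ultrasound
F16	HP:9030003;HP:9110001	ultrasound
F17	HP:9020001;HP:9050002	ultrasound
F18	HP:9030001;HP:9020002	pediatric
F19	HP:9020002;HP:9070001;HP:9050001	postmortem
F20	HP:9020008;HP:9020004;HP:9010005	ultrasound
F21	HP:9040002;HP:9110001	ultrasound
F22	HP:9030003;HP:9010006	pediatric
F23	HP:9010001;HP:9010002;HP:9010003;HP:9010004	postmortem
F25	HP:9030004;HP:9050001	postmortem
F26	HP:9110001;HP:9020001	ultrasound
F27	HP:9030001;HP:9040001	postmortem
F28	HP:9020003;HP:9110001	ultrasound
F29	HP:9010005;HP:9110001	pediatric
F31	HP:9050002;HP:9020001	ultrasound
F32	HP:9110001	ultrasound
F33	HP:9030001;HP:9040001	postmortem
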