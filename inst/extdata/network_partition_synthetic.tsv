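roi_label	network
roi1	DMN
roi2	FPN
roi3	O
roi4	SM
roi5	CO
roi6	DMN
roi7	FPN
roi8	O
roi9	SM
roi10	CO
roi11	DMN
roi12	FPN
roi13	O
roi14	SM
roi15	CO
roi16	DMN
roi17	FPN
roi18	O
roi19	SM
roi20	CO
roi21	DMN
roi22	FPN
roi23	O
roi24	SM
roi25	CO
roi26	DMN
roi27	FPN
roi28	O
roi29	SM
roi30	CO
roi31	DMN
roi32	FPN
roi33	O
roi34	SM
roi35	CO
roi36	DMN
roi37	FPN
roi38	O
roi39	SM
roi40	CO
roi41	DMN
roi42	FPN
roi43	O
roi44	SM
roi45	CO
roi46	DMN
roi47	FPN
roi48	O
roi49	SM
roi50	CO
roi51	DMN
roi52	FPN
roi53	O
roi54	SM
roi55	CO
roi56	DMN
roi57	FPN
roi58	O
roi59	SM
roi60	CO
roi61	DMN
roi62	FPN
roi63	O
roi64	SM
roi65	CO
roi66	DMN
roi67	FPN
roi68	O
roi69	SM
roi70	CO
roi71	DMN
roi72	FPN
roi73	O
roi74	SM
roi75	CO
roi76	DMN
roi77	FPN
roi78	O
roi79	SM
roi80	CO
roi81	DMN
roi82	FPN
roi83	O
roi84	SM
roi85	CO
roi86	DMN
roi87	FPN
roi88	O
roi89	SM
roi90	CO
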