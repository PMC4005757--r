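# Example Y haplogroup tree configuration.
# parent "." marks a root; reduced = 1 marks the cross-study comparison
# level that collapse_haplogroups() sums sub-lineages into.  Edit to the
# lineage panel of your survey.
label	parent	reduced
Y	.	0
R-M343	Y	0
R-M269	R-M343	1
R-L11	R-M269	0
R-P312	R-L11	0
R-U152	R-P312	0
R-U106	R-L11	0
R-M17	Y	1
E-M35	Y	0
E-M78	E-M35	1
E-V13	E-M78	0
E-M81	E-M35	1
G-P15	Y	1
I-M170	Y	1
J-M304	Y	0
J-M267	J-M304	1
J-M172	J-M304	1
J-M410	J-M172	0
J-M67	J-M410	0
J-M92	J-M67	0
J-M12	J-M172	0
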