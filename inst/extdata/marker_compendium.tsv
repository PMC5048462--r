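gene_id	s1	s2	s3	s4	s5	s6a	s6b	s6c	s7	s8	s9a	s9b	s10	s11
AT3G07720	1	1	1	1	1	1	1	1	1	1	1	1	1	1
AT3G58810	1	1	1	1	1	1	1	1	1	1	1	1	1	1
AT4G19690	1	1	1	1	1	1	1	1	1	1	1	1	1	0
AT3G12900	1	1	1	1	1	1	1	1	1	1	1	1	1	0
AT3G61930	1	1	1	1	1	1	1	1	1	1	1	1	1	0
AT1G09560	1	1	1	1	1	1	1	1	1	1	1	1	0	0
AT3G06890	1	1	1	1	1	1	1	1	0	1	1	1	1	0
AT3G46900	1	1	0	1	1	1	1	1	1	1	1	1	1	0
AT3G50740	1	1	1	1	1	1	1	1	0	0	1	1	1	1
AT3G56980	1	1	1	1	1	1	1	1	0	1	1	1	0	1
AT1G56160	1	1	0	1	1	1	1	1	1	1	1	1	1	0
AT3G58060	1	1	1	1	1	1	1	1	0	1	1	1	1	0
AT5G01600	-1	0	-1	-1	-1	-1	-1	-1	0	-1	-1	-1	0	0
AT4G04770	-1	0	-1	-1	-1	-1	-1	-1	0	0	-1	-1	0	0
AT2G36885	-1	0	0	0	-1	-1	-1	-1	0	-1	-1	-1	0	0
AT1G31330	-1	0	-1	-1	0	-1	-1	0	0	0	-1	-1	0	0
AT1G68650	-1	0	0	0	-1	-1	-1	-1	0	-1	0	-1	0	0
AT2G37130	-1	0	-1	-1	0	-1	-1	0	0	0	-1	-1	0	0
AT2G40300	-1	0	0	-1	-1	-1	-1	-1	0	-1	0	0	0	0
AT3G09220	-1	-1	0	0	-1	-1	-1	0	0	0	-1	-1	0	0
AT4G08390	-1	0	-1	-1	0	-1	-1	0	0	0	-1	-1	0	0
AT5G59400	-1	0	-1	-1	-1	-1	-1	-1	0	0	0	0	0	0
AT1G58290	0	0	0	0	-1	-1	-1	-1	0	0	-1	-1	0	0
AT4G25100	-1	-1	0	-1	-1	0	0	-1	0	0	0	0	0	-1
AT5G64100	0	-1	0	-1	0	-1	-1	0	0	0	-1	-1	0	0
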