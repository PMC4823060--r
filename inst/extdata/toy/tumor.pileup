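chr1	150	C	20	.......,,,,,,,AAAaaa	IIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]
chr1	250	A	60	............................,,,,,,,,,,,,,,,,,,,,,,,,,,,CCCcc	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]
chr1	350	C	50	......................,,,,,,,,,,,,,,,,,,,,,,AAAaaa	IIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]
chr1	450	T	50	.......................,,,,,,,,,,,,,,,,,,,,,,AAAaa	00000000000000000000000000000000000000000000000000	]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]]
chr1	550	A	20	.......,,,,,,,CCCccc	IIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]
chr1	650	C	20	........,,,,,,,.+2AG.+2AG.+2AG,+2ag,+2ag	IIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]
chr1	680	G	20	.......,,,,,,,AAAaaa	IIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]
chr1	750	G	17	.....,,,,,.-2TT.-2TT.-2TT.-2TT.-2TT.-2TT.-2TT	IIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]
chr1	1450	C	20	......,,,,,,AAAAaaaa	IIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]
chr1	1700	G	20	.......,,,,,,,AAAaaa	IIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]
chr1	1800	T	20	.......,,,,,,,AAAaaa	IIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]
chr1	1900	C	20	.......,,,,,,,.-2AA.-2AA.-2AA,-2aa,-2aa,-2aa	IIIIIIIIIIIIIIIIIIII	]]]]]]]]]]]]]]]]]]]]
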