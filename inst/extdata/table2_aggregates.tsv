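variable	level	all	positive	negative
total	total	107	27	80
categorical_age	<50	104	25	79
categorical_age	>=50	3	2	1
gender	male	54	15	39
gender	female	53	12	41
localization	colon	79	18	61
localization	rectum	25	7	18
localization	both	2	2	0
localization	not_applicable	1	0	1
sidedness	right	47	12	35
sidedness	left	47	10	37
sidedness	both	7	4	3
sidedness	not_applicable	6	1	5
ihc	loss	14	5	9
ihc	normal	9	3	6
ihc	not_applicable	84	19	66
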