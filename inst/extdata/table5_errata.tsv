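table	patient	printed	normalized	note
table5	p-24	+15q22.2q23<56.84.18-67.10>	56.84-67.10	stray ".18" in start coordinate dropped
table5	p-24	+22q13.1<35.86 = 37.20>	35.86-37.20	"=" read as the range dash
table5	p-24	+16q23.3q24.3[1.8]	1.80	ratio padded to two decimals
table5	p-24	-14q32.3<105.60-105-70>	105.60-105.70	second hyphen read as decimal point
table5	p-21	-3 p24.3p14.3	3p24.3p14.3	stray space inside band span removed
table5	p-21	+21q22.3qter[1.7]	1.70	ratio padded to two decimals
table5	p-22	decimal commas in all four rows	decimal points	e.g. <130,24-134,36>[0,55]
table5	p-32	-3p21.3p21.3<44,20-49,02>	44.20-49.02	decimal commas
table5	p-24	+21q22.1[2.5]	2.50	ratio padded to two decimals
table5	p-25	-14q32.3<105.96-105.94>	105.94-105.96	reversed bounds swapped
table5	p-1	-7<0.14-158.76>	bands pterqter	whole-chromosome loss, band span supplied
table5	p-2	-7<0.14-158.76>	bands pterqter	whole-chromosome loss, band span supplied
table4	t-1	-5q15qter<94.36-177.87[0.79]	<94.36-177.87>	missing ">" restored
table4	t-13	-1q42.3.q44	1q42.3q44	stray dot in band span removed
table4	t-2	+14q11.2q12<24,09-26.24>	24.09-26.24	decimal comma
table4	t-25	[0.69]*.	[0.69]*	trailing period dropped
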