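accession	name	length	class
Q94IM1	22 kDa alpha-zein 14	266	22kDa
P04698	22 kDa alpha-zein 14	267	22kDa
P06679	22 kDa alpha-zein 8b	261	22kDa
P04700	22 kDa alpha-zein 16	263	22kDa
P06678	Zein-alpha 19D1	240	19kDa
P04704	Zein-alpha ZG99	235	19kDa
P06676	Zein-alpha 19C1	240	19kDa
P04703	Zein-alpha A20	240	19kDa
P06674	Zein-alpha 19A2	230	19kDa
P06675	Zein-alpha 19B1	234	19kDa
P04702	Zein-alpha M6	240	19kDa
P02859	Zein-alpha A30	234	19kDa
P04705	Zein-alpha PZ19.1	186	19kDa
Q548E6	19kD alpha zein B3	240	19kDa
Q548E7	19kD alpha zein B2	267	19kDa
B6SIF7	Zein-alpha PMS1	234	19kDa
B6SHV3	Zein-alpha 19B1	234	19kDa
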