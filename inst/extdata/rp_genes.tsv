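# Cytoplasmic ribosomal protein gene registry: symbol, subunit, cytoband.
# One gene per line, tab-separated; cytoband may be empty.
RPL3	large	22q13
RPL4	large	15q22
RPL5	large	1p22
RPL6	large	12q24
RPL7	large	8q21
RPL7A	large	9q34
RPL8	large	8q24
RPL9	large	4p14
RPL10	large	Xq28
RPL10A	large	6p21
RPL11	large	1p36
RPL12	large	9q33
RPL13	large	16q24
RPL13A	large	19q13
RPL14	large	3p22
RPL15	large	3p24
RPL17	large	18q21
RPL18	large	19q13
RPL18A	large	19p13
RPL19	large	17q12
RPL21	large	13q12
RPL22	large	1p36
RPL23	large	17q12
RPL23A	large	17q11
RPL24	large	3q12
RPL26	large	17p13
RPL27	large	17q21
RPL27A	large	11p15
RPL28	large	19q13
RPL29	large	3p21
RPL30	large	8q22
RPL31	large	2q11
RPL32	large	3p25
RPL34	large	4q25
RPL35	large	9q33
RPL35A	large	3q29
RPL36	large	19p13
RPL36A	large	Xq22
RPL37	large	5p13
RPL37A	large	2q35
RPL38	large	17q25
RPL39	large	Xq24
RPL41	large	12q13
RPLP0	large	12q24
RPLP1	large	15q23
RPLP2	large	11p15
UBA52	large	19p13
RPSA	small	3p22
RPS2	small	16p13
RPS3	small	11q13
RPS3A	small	4q31
RPS4X	small	Xq13
RPS4Y1	small	Yp11
RPS5	small	19q13
RPS6	small	9p22
RPS7	small	2p25
RPS8	small	1p34
RPS9	small	19q13
RPS10	small	6p21
RPS11	small	19q13
RPS12	small	6q23
RPS13	small	11p15
RPS14	small	5q33
RPS15	small	19p13
RPS15A	small	16p12
RPS16	small	19q13
RPS17	small	15q25
RPS18	small	6p21
RPS19	small	19q13
RPS20	small	8q12
RPS21	small	20q13
RPS23	small	5q14
RPS24	small	10q22
RPS25	small	11q23
RPS26	small	12q13
RPS27	small	1q21
RPS27A	small	2p16
RPS28	small	19p13
RPS29	small	14q21
FAU	small	11q13
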