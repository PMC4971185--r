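order	family	known_species	captured_species	n_bins
Coleoptera	Carabidae	945	223	263
Coleoptera	Cerambycidae	358	90	125
Coleoptera	Dermestidae	48	8	8
Coleoptera	Heteroceridae	28	6	4
Coleoptera	Scarabaeidae	219	43	60
Coleoptera	Silphidae	26	12	14
Coleoptera	Silvanidae	15	3	3
Coleoptera	Trogidae	15	4	4
Coleoptera	Trogossitidae	22	1	1
Hemiptera	Cicadidae	21	2	3
Hemiptera	Diaspididae	29	2	2
Hemiptera	Gerridae	23	7	8
Hemiptera	Nabidae	20	10	13
Hemiptera	Pentatomidae	69	27	36
Hemiptera	Rhopalidae	16	9	10
Lepidoptera	Erebidae	328	191	216
Lepidoptera	Hesperiidae	81	27	26
Lepidoptera	Lycaenidae	77	36	33
Lepidoptera	Noctuidae	1145	652	641
Lepidoptera	Notodontidae	57	49	54
Lepidoptera	Nymphalidae	110	69	66
Lepidoptera	Papilionidae	18	10	9
Lepidoptera	Pieridae	43	21	11
Lepidoptera	Saturniidae	26	11	9
Lepidoptera	Sphingidae	65	30	34
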