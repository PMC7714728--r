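duplex_id	strand1	strand2	internal_stack	cofold_mfe
d01	UAUUUU	AAAAUA	-5.1	0
d02	AUAUAUA	UAUAUAU	-7.2	-2.1
d03	UCUAUUAA	UUAAUAGA	-10	-5
d04	GAACUACCU	AGGUAGUUC	-16.5	-11.9
d05	AUUUAUAAAG	CUUUAUAAAU	-10.5	-5.9
d06	GUUCACAACCU	AGGUUGUGAAC	-20.4	-15.8
d07	CAACGGAGCCGG	CCGGCUCCGUUG	-27.8	-23.7
d08	CGUCGGGAGGCGU	ACGCCUCCCGACG	-31.8	-27.2
d09	CCGGCGGCGGAGGG	CCCUCCGCCGCCGG	-38.3	-34.2
d10	GGCCCGCGGGGCCGC	GCGGCCCCGCGGGCC	-43.9	-39.8
d11	AAUUUA	UAAAUU	-5.1	0
d12	UAAUGUA	UACAUUA	-8.9	-3.8
d13	UAAUCCUU	AAGGAUUA	-12	-6.9
d14	CCAUACCGC	GCGGUAUGG	-19.1	-15
d15	GCGAGACUUG	CAAGUCUCGC	-20	-15.9
d16	UUCAUGGUACC	GGUACCAUGAA	-20.9	-16.4
d17	CCCGACGAUCCU	AGGAUCGUCGGG	-27.3	-22.7
d18	CCGAGCGCGGACU	AGUCCGCGCUCGG	-31.8	-27.2
d19	CAGGGUUCGCCGCG	CGCGGCGAACCCUG	-33.6	-29.5
d20	CCCCGCCCGCCGCGC	GCGCGGCGGGCGGGG	-43	-38.9
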