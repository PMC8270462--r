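>chr1 synthetic toy contig
CGGTGCGCCTTGTTCGTGCTGTTCGGCTCGATGCCGCTCTGTTAGCTAGAATAACTAGAG
CTTATCGTCCCTGTCGATCGAATTCGTTTCCTACCATCTGAATCTCTTAGATGTGCAAAT
GTTCACATAGACTCGTTATCTTACGCAGCAGGGCGTCCTAAATATGCGTGAGCTCTACTA
CATCGGTAGTCGTCAGCCTCCACGATAGCCTGTTGACGTCAGGCAACCTTGTGCGTGGTC
ATAGCTAGGCAATCTAACTCTTGTGAAGATATGTCAACCATCTAAAGGGGAAAAGGCAAG
NGGGGCGCGGGTCCCAGAGGCAGGCGCACTGATCTCTTGATTGTGCCACTCGGTGCCTCT
TGCTCTTCTGTAAAGTCACCCACCTCTTACTCCTTCGCAGCAAGAAAGGGAGGCCGAGAA
CGCAAGGCCTCTGGCGCAAAGCGTACCTATATCCACTGACTTTCACGAATATTTCTTACT
ATGACAATTTTATCCGCGAGTCAGAAGCCTCACGCTGGTATCTCAGACACATAAAGCACC
ATAGGTGGAGAAATGGGTACGGACAAGGACGATGTCACCCTATTTGCAAACAGCGCTGTA
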