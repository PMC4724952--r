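>TBE1 terminal inverted repeat consensus, 78 bp
CAAAACCCCAAAACCCCTTAATGAGGTTTATAAGTGCTTTGATTTGTAGGGAATTTGTTAGGGGTTGGGG
TTATTAAT
>TBE2.1 terminal inverted repeat consensus, 138 bp
CAAAACCCCAAAACCCTTTCAGTAGTTTGATTGAGTTTTTGATTGATAAAAGTAGACTATTAGTGCATAC
TTTATTAGGGTTTTAATAGGGTTTATGTAGGGGTTTAATGTTTAAATATTAGTAATTTAAGTGAGTAT
>TBE2.2a terminal inverted repeat consensus type 1, 117 bp
CAAAACCCCAAAACCCTTTCAGTAGTTTGATTGAGTTTTTGATTGATAAAAGTAGACTATTAGTGCATAC
TTTATTAGGGTTTTAATAGGGTTTATGTAGGGGTTTAATGTTTAAAT
>TBE2.2b terminal inverted repeat consensus type 2, 112 bp
CAAAACCCCAAAACCCCTGAAGTTGTTTGATTGAGTTTTTGATTGATGAAAGTAGACTATTAACGCATGC
TTTATTAGGGTTTTAATAGGGTTTATGTAGGGGTTTAGGGTT
>TBE3 terminal inverted repeat consensus, 85 bp
CAAAACCCCAAAACCCCTTAGTGAGGTTTATAAGTGCTTTGATTTGTAGGGTATAGTTGGGGTCTTATTG
GGGTTAGTAGAGAAA
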