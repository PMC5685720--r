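>JAK2syn synthetic JAK2-like hotspot fragment
TGGACGTCGTAGGTTGCTGAGCAAGCGATTACGTTCTTCAAACCGATACCGGCGAGTATA
GGATAAATCTCAGCGCGATCGACCTTAAGCTCTGCGTACATGTACCGACCGACGCGAAAT
TAGGGCTCTGGCCAAGCCAATTGAATGGGACGTGTAATGCTCGCCACAACTGTGAGCCAA
ATCGGATCTTCGCGGTAATACTGTCAACACTGATAATCACGAATAGCCACTACTGCTATA
CGATCTTTCTTGCGCATACAAGTGTTTCGACCGCATCTTACCTTACGTGCTTCACACAGC
CCCTATTACCAGGTTCAACAGATTAGATACCTAGAGAAGGCCTGGTTCCCGGCTATAACA
CAACTATTTCCAGTAGACAGGAAACGCTCAGTACCGGCGGCACGACTTAGAAAGAGCTCC
TTCATTGCAGTCGGGAGCAAGCACACGCCTGCGCACCGTATTATCCGAAGTGCCCATCTA
TACAGACGGCCCAGCCCACACTCAGGAAGCCGGCACAATGTGGCACGGAATTTGTTGGGT
AAGCATGCAACGTAAGCAAAAGTGGTTGTGTTTCGCAGTACGAGGAACCGCGAAACGGCC
TGCAAGATCTCCGTCAATTACGACCGGGCTGTATACTGGTTTGGGCTGCGGAACAGGTAG
AGCAACTCAAGTGGCCGATATTCAACTTTACGTACTATTATGTTACTCGTAAATGAACCT
CGATTAGTGAGCCGTAGGCAGTAGTGAGGGGAAACCCGCATGCGGTCGCTTTCTATCATG
GCTCCTCCGGCAACCTTGGCCTGGTCTCACGTCAACGTTATAATAATATTCCCCTCTGGT
TCTATTGAGTCCGAGCTGGAAAGTGCTGCACCGGTTATCATCTTCTTTAACTGGTACTAT
GATAGACACTTATGAGCGACGTTCGGCATGCCTTTCTTTGGAGTGGGTCAGGTCGAAGAT
GATCACGGAACCTGAGACCGCACGCAGCAAGGCGAGTGAGCAGGCCAAGTCGTCTCATTG
CTGCCGGAAAGCACCTTGCGTCTTCAAGAATTCTGTCCACAATGGCTTTCCCGCGGATTA
CGAGCGAATTAGAATTATAACTGCATGTCTACAGCCGTGGCCGGAAGAACGTGAAGCTAC
ACTTGCCGCGCTTCAACGCCAGAGCCCCACTTCCACGGCCGGCTTTTGATTAGTGCGATT
GTGTGTCGCCGCTTCGGATCCCATGGTGGGTTTCCGTACTCATGCAGCACGCTACTCTCA
ATTTGCCCTATTCTACTCGCCCCCGTAGGCTTCGGTGGCTTCAACTGAGTGCCTGCTGCA
GCGGTGCTTTCGCCCCTATGCAGCCGCGTACTGCTGTGGCTTAGCAGGCCAGCATGTTGG
CGGGAGGGCGCAAATAGCATCAACAATGTACGGATAAACTGCGTTATCGTATGATCGTAA
CTGTTGTCAATTTTCAATCTTATTCGAGTCATATGACCCTGAAGCAAAAGCATAGGACAC
TTACTAGCGAAAAAGGCTCACCAGCACCAGATACACATCACAGCGGAGATTTATCACGTC
TGTGACATGGGCGCCTCTTTCTGCGTATGTATCCTGCACATCCACAAATTCATCCCCCAG
TCGTAATTGGGTCCCTGGTGTCGATTAACGCACGGGTGAACTAAGAGCGCACTCCTATAG
AAACTACCCAGCGGAAAACGCGAGTAACTCGGCCTCTAATCCATGATTACTTTTCAAGGC
ACCGTTGACCATTAATGAGTAACGATGAGCGTTCTAGTCGTAACGGACATACTTAATAAT
TAGTTGTCATGTCACATTGGTGAGCTATTCTAGTTGTCATGGTATGCGGGGGTAGACTCT
TTCTATCGGACCTAAATTAGTCTCTCTATTACAGAAGTTGCCCACTGGTCGCAACGTCAT
CAACATAGCGGTATCCAATTTATGAGGACGTCCCTGTAGGTCCAAAGGTGGCAAGCCGGG
TCTTTCTGACGTAAAAACTA
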