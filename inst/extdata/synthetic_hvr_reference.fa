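>HVR1_synthetic region=15977-16399 note=synthetic stand-in, not rCRS
TTGGCTAATTTTTAAGATCCCACACGTAGCTTCCTTTTCGAGACCCTTAAGTAGCTACTC
ACCATGTCAAACCTGCTCCACCATCCCTTACAACACCCGCCACTTTCAATTCCTATTAAA
AATACATGACGACGAATTTAATTTTACTACCAGGTACCTTAAGACTCACGCTACCGCGGT
ATCAGTGTTTTGTAATCTTAAGCGGGCACGCGTTGCCAACGACCATTTTACGCCCCCACT
TCCTCCCCCCGTCCCCACCTTTTCAATACCACACAACTATCACGCTCCACCCACTCTATG
AGCACGTTCAGTTCCCCCACATACGGCTCAACAATCTCTAAGGACCCCCATTAAGACAAT
TCGTATAACACTGCCCTAGCGCGGTTCAACAAGAGCTCATCAGACGATTACAGCCCGGAC
GTT
>HVR2_synthetic region=29-381 note=synthetic stand-in, not rCRS
TCGTCGTCCTTCCTGACCGGACCAACTCTATTGATTACCGTCATAGTCTACCAATACCAC
TCAGTCAAACCCTATCTGAGAACTATTAATTTCCATATAGCCACTATTTACATCAATTCA
ACTTCTCGCGCAATTCGAAGCCATCCTCCGAGACAATCACTCTCTCTCGCCCTTCTCGGC
TACACAGATCACACAGTCCAACCTACTTACTTTATCAACAAAGAAATCGTACAGAACATC
CGACTGCTTAACCCCTTTTCCAACAATTACCAAACCCCCCCTCCCCCAAATAGAGAGCAT
TCACACGATGGAGGGACCACGCGAGACCAAATACAAGCTAATTCATCCTAAAC
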