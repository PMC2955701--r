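>mir01_pos001
CCCCAAUUAUGUGGCAUUCCAUUCCAGGAAAUGACCUGUUUAUUUAUAUAUGAGUACUAGGUAUUCAUAGUGCUUCAUGGAAUCACCAGGAUUAAACCUGUUAUAGAAAAUAUCUACUAGGAAAAUAAUGACUUUAGCCACGCACAACCAGGAUUAUACCUGUUAUUAAUUAUAUUUUGGCUCCCAAUU
>mir01_pos002
UGGCGACAAACAACACCUUAGACCUUGUACCAGGAAUGCUUUUGUUAAACAUAUAAUAAUCCCUGAACGCAAUUCUAUCGAUGGUCACGUCAGGGCACAAACGCUGCUGGUUACACUAUCGUAAUUUCUAACCGGCUUCGGAGUUUAAUUUACAAGUGGCCCGAUCAUCUAACCAUCGCAAGGGCCCGGUCAACUUGUAGGAUCAAAUUCGCCCGACAGUGUUACG
>mir01_pos003
AUACUGCACUAAUCCCUCCUUCUUAUUUGCGGACCAGGAAUACGACGGUUAGUUAGUUUAAGGUGGCGAAAUGUGGAUUCGGAACAUCGUCUGUCCGUCCAGGAAGUAACCUGUUAAACGAUAUUACCAGAAGAAGUACCAAAAAGCAGCAUAGGCUGCAUUUACCAGGAGGAAGUUUGUUUUUAAUGAAUUCGAAAGUGAGAAUUACACGGUCUA
>mir01_neg001
UUCUGCUAAACUAACUCAGAAUUAAAAAGUCAAGUUGCUCCCAAGGGAAGGCGCCAACGUAAAUAGAAAACUGGUAGUCGCAGCGAUGAGAUACUCGAGAUCAACGUAUGAGGGCCAGUGCCUGAGCCACUCGCAUGGAGUGAGAGCAGUGAGUCCCCACUCAGGACACUUACCAGACGACUUACACGGCGCGAAAUAAGCUAUGUGCAGGGAAUCGCGGUUCGUACCGGCU
>mir01_neg002
UGCCGCCGCAUGCUCUAUACUACGCAUACAAUACCCGUCAGAAUCACUAUGUCCUUCUUGAUCACGAGGUCACGAAGUCUCUGUAGGAUCAAAGUAGGGGGGCAGAGUACGAAUAAGAACGGGCUAGUGUCGCGGAACGAAACUACAACGAAUCUCUAUGGUCGGGAUUUCCAACCGGCACGAAGGUUGACAGGCACCAACACGACGUAUUAGGCAAGCUGC
>mir01_neg003
GCAAAUCCAUAUAGUCCAGCUGGUCGCUUUAGAAUUCUGAAGGGUAGGUUGGAAAGUGGAUUUUCUCGUACUCAUAUUCACUCUGGAGUGCCUCGCAUCCGCUGUCGACUAACCGCGGUCUCAACAACGACCACUUAACUUACGCGAAAGAGGGCAAUGAGACAUGAGCAUUGCGCUAACACGACGCAAUAAAUUCGUGGUGGGCAAGAAAGG
>mir02_pos001
CUCAUGUCCGUUCGCGGUUUACCACCCGCUCUUUGUGGAUUCCUGGUAUAUGAAAAUAGGCAACGAACGAGAGAGGGGCAGGUUUCUGUGAGUACAACAAACCGCUGCGCCCUCUGACACUAUGGGGGAUUGUGACUAUACGAGCCCAGCAUGCUAAAACCUGAAAGGGGAAAGAAACUUUUUUGCGUCGGCA
>mir02_pos002
CCUCGGAUACGUCUCAGAACCGAAACCUGAUGAGAGACAAGCAUGAUAAUUUGUCUGUGUCACACUCACUACAAGCACAGGACUUAACCUGAUCUGAGAAAGAUUUUAUAAACUAUACUGCUUCUGCGCACCGGCGCGAGCAGUGCGUGUAAGCUCGCGACGCGAAAAGAAAUACACUGUUAUUGGUCAU
>mir02_pos003
GGAGCGAGCCCUUUUGUGGCCCCGUCACACAGCGCUUCGACCACCGAAAACACUCAUAUUGGGUGUUGGUCCACAACAAUUCGAACCAGCUACCCUCUGGAACCUGAUAGGAGAAAGCAAAAAUUAUACGGGAUCUUAGUUACUAAUGAGACCGCUGGAACGUACCAAAACCUGUUAGGGGAAAGUUUUACUGGCUUCAACGGUACC
>mir02_neg001
CGUAAAUUGUGCCCACUCCACUACAGCUCGUUUGGCAUUUACAACCGCAAGACGUCUAUGACUCAUAGGCUUUCGCUCCACACCGAUCGCUUCUAGUUGCCCUAGUACCCCCAGAUAUCUCCAAUUCUAUUUCGGAUCUUGAUGCUUGGAUGCCUGAACUCAGCAGUGAACCUAUUACCAUUACACAGUACGAUGGUUGUUCGUUUUGAUUCUCACA
>mir02_neg002
GCCGAUACCCAUACGAGGUCCCUGCCCGUCUCCAUAGCAGCAUACCGAGGCCUCAGGUGACUCGCACGUAGGUGCGCGGCUAAACGUGGCGAACACUUAAAACUACGCACGUCCAGCAACUGCCUAACCAGGCAUAGCACUCAGGCAUAUGGAGUCAUGUCGGUCGUUGCACUCCCCUUCAUCCGGCUUCCAUUCUG
>mir02_neg003
CGCAGACAUAUCCAGCAACUUGCAGUCUAUUGGGACUGCCAUGACCCUGGCUGAUCCCUUUGGCCGCGGCAAUUCUGCCUUUAUCUUAUUGUAUAUUCGGGUAUUCCAGCCACUGUCUGUAAUACGAUGACAUUUCAUUAUAUUGGUAUUUUACUUUCCAUUCUGCCCGCGACACUGAUGGUGCUCCACAAUUGUGUGGACAGUGGCGCGU
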