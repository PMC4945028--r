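probe	orientation	sequence
high_affinity	forward	CGGGCCAGCTGCTGTCTCGCTCGCACCCGCACCGCT
high_affinity	reverse	AGCGGTGCGGGTGCGAGCGAGACAGCAGCTGGCCCG
constant_flank	forward	CTACTATAGCAATGGGAGCGAGAAGTATCAGTCAGT
constant_flank	reverse	ACTGACTGATACTTCTCGCTCCCATTGCTATAGTAG
four_repeat	forward	GTATTGTTTATTTATGTAATTATAATGAGAGAGATATTGTTTATTTATTAATGTATAATT
four_repeat	reverse	AATTATACATTAATAAATAAACAATATCTCTCTCATTATAATTACATAAATAAACAATAC
eight_repeat	forward	TGTTTATTTATGTAATTATAATGAGAGAGAGAGAGAGATATTGTTTATTTATTAATGTAT
eight_repeat	reverse	ATACATTAATAAATAAACAATATCTCTCTCTCTCTCTCATTATAATTACATAAATAAACA
ten_repeat	forward	TTTATTTATGTAATTATAATGAGAGAGAGAGAGAGAGAGATATTGTTTATTTATTAATGT
ten_repeat	reverse	ACATTAATAAATAAACAATATCTCTCTCTCTCTCTCTCTCATTATAATTACATAAATAAA
fifteen_repeat	forward	TTATGTAATTATAATGAGAGAGAGAGAGAGAGAGAGAGAGAGAGATATTGTTTATTTATT
fifteen_repeat	reverse	AATAAATAAACAATATCTCTCTCTCTCTCTCTCTCTCTCTCTCTCATTATAATTACATAA
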