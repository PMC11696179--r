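>FT_promoter_CORE_fragment 169 nt, carries the four CO response elements
TATTTCCAGTGTATTAGTGTGGTGGGTTTGGAATACCACAAACAGAAATAAAAAGAAAGAAAAATATGAAATAAGACGACAATGTGTGATGTACGTAGAATCAGTTTTAGATTCTAGTACATCAATAGACAAGAAAAAGATTGTGGTTATGATTTCACCGACCCGAGTT
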