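# Common lncRNA subsequences and their complementary sequences as reported by
# the originating microarray study of brain perivascular astrogliosis.
index	sequence	n_bases	complement
1	UUCUUUCACAUA	12	UAUGUGAAAGAA
2	UCUCAGUGUCGUUAU	15	AUAACGACACUGAGA
3	ACGGACCAGGUA	12	UACCUGGUCCGU
4	AUCAUCUUUCC	11	GGAAAGAUGAU
5	AGCCACAGUUCUGU	14	ACAGAACUGUGGCU
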