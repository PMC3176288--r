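label	forward	reverse
miR34b	GAATTTGGGTTTTTATTTTTTAGG	CCAAACCCTAAAACTAACTCTCTC
let7i	GGGGGTAGTTTAGAATTAGTTGGTGTTTG	CCCCTTCTTTTCCTTTACCTTCCC
miR124a	GGAAAGGGGAGAAGTGTGGG	CACCGCGTACCTTAATTATATAAAC
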