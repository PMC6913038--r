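gene_id	symbol	chrom	start	end
ENSBTAG00000014411	TMEM263	5	70573524	70593134
ENSBTAG00000010144	MTERF2	5	70596429	70602003
ENSBTAG00000010149	CRY1	5	70606115	70701030
ENSBTAG00000037306	ENSBTAG00000037306	5	70793315	70793420
ENSBTAG00000027064	BTBD11	5	70923456	71257389
ENSBTAG00000004654	PWP1	5	71280815	71300027
ENSBTAG00000012999	PRDM4	5	71324566	71347630
ENSBTAG00000011070	RTCB	5	71366686	71388046
ENSBTAG00000011071	BPIFC	5	71391550	71427743
ENSBTAG00000020636	SYN3	5	71475847	71926718
ENSBTAG00000021953	LARGE1	5	72157229	72769395
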