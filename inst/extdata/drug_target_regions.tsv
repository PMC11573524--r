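chrom	start	end	gene_symbol
19	11200038	11244506	LDLR
5	74632154	74657929	HMGCR
7	44552134	44580914	NPC1L1
1	55505221	55530525	PCSK9
2	21224301	21266945	APOB
2	44039611	44065923	ABCG5
2	44066103	44105605	ABCG8
8	19796764	19824770	LPL
11	116700422	116703788	APOC3
22	46546429	46639653	PPARA
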