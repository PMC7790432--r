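phylum	n_otus
Dinoflagellata	206
Cercozoa	140
Stramenopiles_X	51
Fungi	20
Apicomplexa	19
Mesomycetozoa	14
Ciliophora	5
Metazoa	3
Lobosa	2
Perkinsea	1
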