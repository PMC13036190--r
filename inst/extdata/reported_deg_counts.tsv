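quantity	value
detected_degs	11002
l_degs	911
s_degs	814
ls_degs	5528
inverse_ls_degs	454
immune_response_degs	985
immune_response_ls_degs	548
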