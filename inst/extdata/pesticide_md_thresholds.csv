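dataset,threshold_nir,threshold_mir
deltamethrin,8.239,7.517
emamectin_benzoate,9.154,5.705
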