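dataset,sample,md_nir,md_mir
deltamethrin,1,2.731,2.454
deltamethrin,2,2.157,1.904
deltamethrin,3,2.213,2.112
deltamethrin,4,3.441,3.017
deltamethrin,5,2.886,3.489
deltamethrin,6,2.183,2.661
deltamethrin,7,3.758,2.961
deltamethrin,8,1.523,2.310
deltamethrin,9,2.92,1.700
deltamethrin,10,3.7,3.808
deltamethrin,11,2.624,2.925
deltamethrin,12,1.9,1.254
deltamethrin,13,2.135,1.843
deltamethrin,14,2.477,1.797
deltamethrin,15,2.423,1.870
emamectin_benzoate,1,5.463,4.092
emamectin_benzoate,2,3.267,2.244
emamectin_benzoate,3,7.631,1.206
emamectin_benzoate,4,3.468,1.633
emamectin_benzoate,5,8.283,1.692
emamectin_benzoate,6,2.229,2.155
emamectin_benzoate,7,3.055,1.953
emamectin_benzoate,8,1.899,1.892
emamectin_benzoate,9,4.962,1.723
emamectin_benzoate,10,1.914,1.829
emamectin_benzoate,11,3.183,0.883
emamectin_benzoate,12,2.947,1.531
emamectin_benzoate,13,3.459,1.785
emamectin_benzoate,14,3.086,1.411
emamectin_benzoate,15,2.613,1.922
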