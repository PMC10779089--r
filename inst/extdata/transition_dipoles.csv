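system,X,Y,Z,Total
Fenoprofen (water),0.0917,-0.5624,-0.4419,0.7211
Fenoprofen-BCyD,-0.0456,-0.0700,0.1518,0.1732
Fenbufen (water),-0.9793,-0.8206,-0.4739,1.3627
Fenbufen-BCyD,0.0105,-0.1213,0.2067,0.2398
Nimesulide (water),0.5110,0.2802,0.2288,0.6261
Nimesulide-BCyD,-0.5166,-0.3848,-1.3888,1.5309
Bifonazole (water),-0.3578,-0.2423,-0.0594,0.4361
Bifonazole-BCyD biphenyl in ring,-0.0514,0.7572,-0.7827,1.0902
Bifonazole-BCyD phenyl in ring,-1.3510,1.9622,-3.2134,4.0002
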