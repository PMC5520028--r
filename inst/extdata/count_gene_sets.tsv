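category	genes
fermentation	ackA|pta|ldh|adhE|pflB|buk|ptb|por
complex_carbon	celA|bglB|xynA|chiA|amyA|pulA|manB|pelA
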