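species	A	T	C	G
Polypedates_impresus	30.2	30.8	14.7	24.3
Polypedates_mutus	30.5	30.4	14.5	24.6
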