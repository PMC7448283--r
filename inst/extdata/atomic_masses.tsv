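# Monoisotopic atomic masses (Da), IUPAC/CODATA. version 1
element	mass
H	1.00782503207
C	12.0
N	14.0030740048
O	15.9949146196
Na	22.9897692809
P	30.97376163
S	31.97207100
Fe	55.93493750
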