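# Synthetic reference table of A-domain binding-pocket signatures (10-char
# codes) -> incorporated substrate. These are constructed stand-in codes for
# testing and demonstration, not experimentally determined signatures; the
# invariant Asp/Lys bookends of real pocket codes are retained. version 1
substrate	code
Val	DAFWIGGTFK
Ile	DGFFLGVVYK
Gly	DILQLGLIWK
Ala	DLFNNALTYK
Leu	DAWFLGNVVK
Trp	DVWNVGMVHK
Tyr	DGTITAEVAK
Phe	DAWTIAAICK
Pro	DVQLIAHVVK
Asn	DLTKLGEVGK
Gln	DAQDLGVVNK
Orn	DVGEIGSIDK
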