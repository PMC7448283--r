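# Synthetic A-domain code tables for two NRPS clusters: a 15-module
# gramicidin-type reference cluster (lgr) and a 17-module britacidin-type
# query cluster (bri) carrying two extra modules (chemical positions 7 and 8)
# and a divergent position-11 code. Codes are constructed stand-ins (see
# stachelhaus_reference_synthetic.tsv), not transcribed genome annotations.
# known_substrate = residue observed at that chemical position. version 1
cluster_id	gene	module_index	code	known_substrate
lgr	lgrA	1	DAFWIGGTFK	Val
lgr	lgrA	2	DILQLGLIWK	Gly
lgr	lgrB	3	DLFNNALTYK	Ala
lgr	lgrB	4	DAWFLGNVVK	Leu
lgr	lgrB	5	DLFNNALTYK	Ala
lgr	lgrB	6	DAFWIGGTFK	Val
lgr	lgrC	7	DAFWIGGTFK	Val
lgr	lgrC	8	DAFWIGGTFK	Val
lgr	lgrC	9	DVWNVGMVHK	Trp
lgr	lgrC	10	DAWFLGNVVK	Leu
lgr	lgrD	11	DVWNVGMVHK	Trp
lgr	lgrD	12	DAWFLGNVVK	Leu
lgr	lgrD	13	DVWNVGMVHK	Trp
lgr	lgrD	14	DAWFLGNVVK	Leu
lgr	lgrD	15	DVWNVGMVHK	Trp
bri	briA	1	DGFFIGVVYK	Ile
bri	briA	2	DILQLGLVWK	Gly
bri	briB	3	DLFNNALTYK	Ala
bri	briB	4	DAWFLGNVIK	Leu
bri	briB	5	DLFNNGLTYK	Ala
bri	briB	6	DAFWIGGTFK	Val
bri	briB	7	DLFNNALSYK	Ala
bri	briB	8	DAFWLGGTFK	Val
bri	briC	9	DAFWIGGTLK	Val
bri	briC	10	DAFWIGGTFK	Val
bri	briC	11	DGTITAEVAK	Tyr
bri	briC	12	DAWFLGNVVK	Leu
bri	briD	13	DVWNVGMVYK	Trp
bri	briD	14	DAWFMGNVVK	Leu
bri	briD	15	DVWNVGMVHK	Trp
bri	briD	16	DAWFLGNVVK	Leu
bri	briD	17	DVWNIGMVHK	Trp
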