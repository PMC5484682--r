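feature_id	gene_title	rho	adj_p
ADORA3	adenosine A3 receptor	0.463	3.04e-04
ATP10A	ATPase, class V, type 10A	-0.541	3.58e-05
CBLB	Cas-Br-M (murine) ecotropic retroviral transforming sequence b	-0.483	1.75e-04
EFHA2	EF-hand domain family, member A2	-0.505	9.48e-05
ERCC6L2	excision repair cross-complementation group 6-like 2	-0.508	8.92e-05
FIGNL1	fidgetin-like 1	-0.565	1.77e-05
GALNT12	polypeptide N-acetylgalactosaminyltransferase 12	-0.688	7.40e-08
IL6ST	interleukin 6 signal transducer (gp130, oncostatin M receptor)	-0.470	2.52e-04
ITGA6	integrin, alpha 6	-0.510	8.18e-05
MBTPS1	membrane-bound transcription factor peptidase, site 1	-0.512	7.89e-05
MTERFD2	MTERF domain containing 2	-0.533	4.31e-05
SATB1	SATB homeobox 1	-0.457	3.65e-04
SORCS3	sortilin-related VPS10 domain containing receptor 3	-0.457	3.62e-04
STAT4	signal transducer and activator of transcription 4	-0.500	1.11e-04
TMEM263	transmembrane protein 263	-0.463	3.06e-04
URI1	URI1, prefoldin-like chaperone	-0.503	1.01e-04
ZFYVE9	zinc finger, FYVE domain containing 9	-0.478	2.01e-04
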