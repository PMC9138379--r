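name	pattern	function	place_id
ABRELATERD1	ACGTG	Element required for etiolation-induced expression of the gene responsive to dehydration	S000414
ABRERATCAL	MACGYGB	Repeated sequence motif in upstream regions of Ca(2+)-responsive upregulated genes	S000507
ACGTATERD1	ACGT	Sequence required for etiolation-induced expression	S000415
ARFAT	TGTCTC	ARF (auxin response factor) binding site of primary/early auxin response genes	S000270
CBFHV	RYCGAC	Dehydration-responsive element	S000497
CGACGOSAMY3	CGACG	Coupling element for the G box element	S000205
CGCGBOXAT	VCGCGB	Element in promoters of many genes	S000501
CRTDREHVCBF2	GTCGAC	Core CRT/DRE motif	S000411
CURECORECR	GTAC	Core of a copper-response element	S000493
DOFCOREZM	AAAG	Core site required for binding of Dof	S000265
DPBFCOREDCDC3	ACACNNG	Binding core sequence of bZIP transcription factors	S000292
DRECRTCOREAT	RCCGAC	Core motif of dehydration-responsive element/C-repeat cis-acting element	S000418
ERELEE4	AWTTCAAA	Ethylene responsive element	S000037
GATABOX	GATA	Motif required for high-level, light-regulated, and tissue-specific expression	S000039
HEXAMERATH4	CCGTCG	Hexamer motif of histone H4 promoter	S000146
LTRE1HVBLT49	CCGAAA	Low-temperature-responsive element	S000250
LTRECOREATCOR15	CCGAC	Core of low temperature-responsive element	S000153
MYB2CONSENSUSAT	YAACKG	MYB recognition site	S000409
MYBCORE	CNGTTR	Binding site for animal and plant MYB proteins	S000176
MYBCOREATCYCB1	AACGG	Myb core	S000502
MYBST1	GGATA	Core motif of MYB binding site	S000180
NODCON2GM	CTCTT	Putative nodulin consensus sequence	S000462
OSE2ROOTNODULE	CTCTT	Consensus motif of organ-specific elements of promoters activated in infected root-nodule cells	S000468
PALBOXAPC	CCGTCC	Box A	S000137
REALPHALGLHCB21	AACCAA	Motif required for phytochrome regulation	S000362
RHERPATEXPA7	KCACGW	Right part of root hair-specific cis-elements	S000512
SEBFCONSSTPR10A	YTGTCWC	Binding site of the silencing element binding factor	S000391
SORLIP2AT	GGGCC	Sequence over-represented in light-induced promoters	S000483
SURECOREATSULTR11	GAGAC	Core of sulfur-responsive element	S000499
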