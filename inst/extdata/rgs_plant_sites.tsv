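# Plant 7TM-RGS phosphosites transcribed from in-text lists.
# The ambiguous AtRGS1 'S435/436' doublet is recorded at 436 (the
# summary-figure convention); residue 435 is also serine in the
# synthetic stand-in sequence.
protein_id	native_pos	residue	ptm_type	known_function	evidence	source
AtRGS1	339	S	phosphorylation	0		RLK
AtRGS1	365	S	phosphorylation	0		RLK
AtRGS1	375	T	phosphorylation	0		RLK
AtRGS1	379	T	phosphorylation	0		RLK
AtRGS1	417	S	phosphorylation	0		RLK
AtRGS1	428	S	phosphorylation	1		RLK;WNK8
AtRGS1	436	S	phosphorylation	1		WNK8
AtRGS1	453	S	phosphorylation	0		RLK
GmRGS2	267	T	phosphorylation	1		NFR1
GmRGS2	269	S	phosphorylation	0		NFR1
GmRGS2	277	S	phosphorylation	0		NFR1
GmRGS2	405	S	phosphorylation	0		NFR1
GmRGS2	428	T	phosphorylation	0		NFR1
GmRGS2	437	S	phosphorylation	1		NFR1
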