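# Ubiquitin-capable lysines proximal to plant phosphosites (crosstalk
# candidates, annotated not observed).
protein_id	native_pos	residue	ptm_type	known_function	evidence	source
GmRGS2	410	K	ubiquitination	0		annotated
AtRGS1	411	K	ubiquitination	0		annotated
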