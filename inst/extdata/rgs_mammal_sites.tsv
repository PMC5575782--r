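# Mammalian RGS functional phosphosites (positions transcribed from
# in-text lists); sequences they refer to are synthetic stand-ins.
protein_id	native_pos	residue	ptm_type	known_function	evidence	source
hRGS2	46	S	phosphorylation	1		PKG1a
rRGS4	103	S	phosphorylation	1		ERK
hRGS5	166	S	phosphorylation	1		curated
hRGS7	434	S	phosphorylation	1		curated
hRGS10	168	S	phosphorylation	1		PKA
hRGS16	168	Y	phosphorylation	1		curated
hRGS18	216	S	phosphorylation	1		curated
hRGS18	218	S	phosphorylation	1		curated
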