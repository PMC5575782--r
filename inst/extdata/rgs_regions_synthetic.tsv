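# 1-based inclusive intervals; native scope = protein coordinates.
# RGS_domain_proximal extends the AtRGS1 domain by the immediately
# adjacent acceptor position used in the domain-enrichment comparison.
name	scope	protein_id	start	end
RGS_domain	native	AtRGS1	288	416
RGS_domain	native	GmRGS2	299	427
RGS_domain_proximal	native	AtRGS1	288	417
cytoplasmic	native	AtRGS1	250	459
cytoplasmic	native	GmRGS2	240	450
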