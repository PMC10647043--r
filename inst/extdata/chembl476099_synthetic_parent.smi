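CNC(=O)c1ccc2cc(OCCCN3CCCCC3)ccc2c1	CHEMBL476099_synthetic	8.0
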