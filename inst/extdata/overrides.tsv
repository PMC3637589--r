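# Phenotype override registry: taxon label -> forced phenotype class.
# Overrides never alter the genotype class.
taxon	phenotype	note
Palaeognathae	VS	MSP of the ostrich retina shows violet-type SWS1 single cones; direct evidence takes priority over sequence-based inference
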