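# Ordered lambda-max rule table for avian SWS1 tuning-site genotypes.
# First matching rule wins; '*' is a wildcard. Point estimates (lambda_nm)
# are configuration values with provenance notes from the site-directed
# mutagenesis literature; class intervals are UVS 355-380 nm, VS 402-426 nm.
res86	res90	res93	class	lambda_nm	low_nm	high_nm	note
F	C	*	UVS	370	355	380	F86+C90 palaeognath-type genotype; unprotonated Schiff base (Wilkie et al. 2000; Yokoyama et al. 2000)
*	C	*	UVS	372	355	380	C90 confers UV sensitivity (Wilkie et al. 2000; Yokoyama et al. 2000)
F	*	*	UVS	369	355	380	S86F shifts VS pigeon/chicken pigments into the UV (Carvalho et al. 2007)
S	S	*	VS	406	402	426	S86+S90 violet-type genotype (Wilkie et al. 2000; Yokoyama et al. 2000)
A	S	*	VS	406	402	426	A86 observed with S90 in violet-type pigments
I	S	*	VS	406	402	426	I86 observed with S90 in violet-type pigments
C	S	*	VS	406	402	426	C86 observed with S90 in violet-type pigments
T	S	*	VS	406	402	426	T86 observed with S90 in violet-type pigments
M	S	*	VS	406	402	426	M86 observed with S90 in violet-type pigments
*	*	*	INDETERMINATE	NA	NA	NA	fallback: unlisted combination or unknown deciding residue
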