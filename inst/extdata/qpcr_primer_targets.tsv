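target	role	description
Actb	reference	beta-actin housekeeping gene used to normalize Ct values
TERRA_chr2	subtelomeric	chromosome 2 subtelomeric TERRA primer pair
TERRA_chr3	subtelomeric	chromosome 3 subtelomeric TERRA primer pair (Wls locus)
TERRA_chr5	subtelomeric	chromosome 5 subtelomeric TERRA primer pair
TERRA_chr8	subtelomeric	chromosome 8 subtelomeric TERRA primer pair
TERRA_PAR	subtelomeric	X/Y pseudoautosomal-region TERRA primer pair
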