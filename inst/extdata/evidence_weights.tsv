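criterion	label	ad_only	weight
additional_case	Additional unrelated affected individual with a qualifying variant in the same gene and an overlapping phenotype	FALSE	1
segregation	Co-segregation with disease in additional affected relatives	FALSE	1
functional_variant	In vitro or cellular evidence of a deleterious variant effect	FALSE	1
model_organism	Model organism or cellular model recapitulating the phenotype	FALSE	1
phenotype_specificity	Distinctive, highly specific clinical presentation	FALSE	1
expression_pathway	Supportive tissue expression or pathway membership (supportive only)	FALSE	0
de_novo	Confirmed de novo occurrence	TRUE	1
lof_constraint	Loss-of-function constraint in gnomAD (high pLI / low LOEUF)	TRUE	1
missense_constraint	Missense constraint in gnomAD (high missense Z)	TRUE	1
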