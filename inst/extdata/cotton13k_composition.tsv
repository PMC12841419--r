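group	category	count
source	gwas_functional	4913
source	resequencing	8658
trait	yield	656
trait	fiber_quality	1987
trait	agronomic	965
trait	abiotic_stress	1126
trait	biotic_stress	179
region	intergenic	8361
region	upstream	2814
region	downstream	1707
region	exon	414
region	intron	205
region	utr	70
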