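sample	role	snvs	high_quality_snvs	nsss_csnvs	nsss_on_region	unique_nsss_on_region
background	background	412362	88593	21745	2851	25
mut1	mutant	849658	456778	35172	6544	863
mut2	mutant	647655	427332	25054	5252	533
mut3	mutant	657987	231449	32114	4913	48
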