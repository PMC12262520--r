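bin	lower	upper
1	0	81.4984788764904
2	81.4984788764904	129.996400321875
3	129.996400321875	195.195858343063
4	195.195858343063	Inf
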