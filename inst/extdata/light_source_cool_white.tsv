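bin_nm	fraction
400	0.02
420	0.03
440	0.04
460	0.04
480	0.05
500	0.06
520	0.07
540	0.09
560	0.12
580	0.13
600	0.11
620	0.09
640	0.07
660	0.05
680	0.03
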