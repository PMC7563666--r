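# Structural variants of the LG23 oaz1-dot1l region in wild Nile tilapia
# males (Kpandu and Koka), called from pooled whole-genome read depth and
# paired-end evidence against the XX female reference genome.
# ci = half-width (bp) of the confidence interval around each breakpoint.
population	start	end	ci	type	shared
Koka	34491225	34512737	50	duplication	yes
Koka	34493315	34498588	390	deletion	yes
Koka	34503117	34509103	852	deletion	yes
Kpandu	34491225	34512741	50	duplication	yes
Kpandu	34491681	34491957	2	deletion	no
Kpandu	34493315	34498548	150	deletion	yes
Kpandu	34499596	34499830	3	deletion	no
Kpandu	34503494	34509103	2	deletion	yes
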