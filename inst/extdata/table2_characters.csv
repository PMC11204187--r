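index,description,n_states
1,ScA crossing the subcostal area (absent/present),2
2,ScP redirected to the anterior margin near the apex (no/yes),2
3,oblique vein between RP and MA (none / joins mid free RP / joins base of free RP / replaced by long curved cross veins),4
4,base of RP distant from base of MA (no/yes),2
5,course of RP (to posterior margin / posterior then anterior / to anterior margin),3
6,RP branching point (distal/basal),2
7,R fork position (distal of 3/5 of wing / nearer the middle),2
8,shape of area between RA and RP (lancet-like/rectangular),2
9,MP basally curved (no/yes; state wording garbled in the source table and stored as free text),2
10,free CuA at least three times the free M (no/yes),2
11,MA shape (undulate/arched/obliquely straight),3
12,widest point of the R-MA area (before R fork / at R fork / after R fork),3
13,MP course (sigmoidal/straight/bowed posteriad),3
14,CuA departure from M+CuA (near 1/3 of wing / distal of 2/5),2
15,MA opposite RP (bowed close to RP / distant from RP),2
16,CuA-CuPa-alpha fusion point (basal half/distal half),2
17,basal cross veins between CuPb and CuPa-beta (strongly curved/straight),2
18,M fork position (basal of 2/5 / at or distal of 1/2),2
19,M+CuA divergence (near 1/3 / near 2/5 / near middle),3
20,free CuPa-alpha vs free CuA length (longer/approximately equal),2
21,basal CuPb-CuPa area width (like CuPa-M+CuA area / distinctly narrower),2
22,handle length vs free CuA (shorter/equal/distinctly longer),3
23,CuPa fork position relative to AA1 bow (at CuPb+AA1 fusion / at the bow / distal of the bow),3
24,handle vs CuPa-beta segment between CuPa and handle (shorter / similar up to twice / more than twice),3
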