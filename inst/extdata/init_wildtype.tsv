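Ini	 0.0383
Elong	 0.0000
Zring	 0.0000
hCori	 0.0000
hccrM	 0.0000
hctrA	 0.0000
IccrM	 0.0000
mccrM	 0.1730
mdnaA	 3.1540
mgcrA	 4.5250
msciP	 6.3350
mctrA	 0.6580
CcrM	 0.4350
DnaA	 2.6380
GcrA	 3.8410
SciP	12.4850
CtrA	 1.9730
CtrAP	 3.9600
CckAP	 0.0420
Complex1	 0.2110
CpdR	 1.0450
CpdRP	 0.0420
Complex2	 0.1870
RcdA	 0.7890
Complex3	 3.4070
PleD	 0.5260
PleDP	 0.6630
PdeA	 0.2280
cdG	 0.5110
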