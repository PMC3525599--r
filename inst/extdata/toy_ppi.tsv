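# synthetic toy interaction network (hand-built example, not real data)
# vertices: atp1 atp2 atp3 atp4 atp5 rad51 rad52 rad54 mre11 xrs2 spo11 yku70 yku80 lig4 nej1
atp1	atp2
atp1	atp3
atp1	atp4
atp2	atp3
atp2	atp4
atp3	atp4
atp4	atp5
rad51	rad52
rad51	rad54
rad51	mre11
rad52	rad54
rad52	mre11
rad54	mre11
mre11	xrs2
xrs2	spo11
spo11	rad51
yku70	yku80
yku70	lig4
yku80	lig4
lig4	nej1
atp5	rad51
nej1	atp1
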