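dimer	partner_a	partner_b	bridge	pos_a	res_a	pos_b	res_b	note
h14-3-3z/h14-3-3z	h14-3-3z	h14-3-3z	R18-E89	18	R	89	E	human zeta homodimer interface bridge
h14-3-3z/h14-3-3z	h14-3-3z	h14-3-3z	E5-K74	5	E	74	K	human zeta homodimer interface bridge
h14-3-3z/h14-3-3z	h14-3-3z	h14-3-3z	D21-K85	21	D	85	K	human zeta homodimer interface bridge
LeoII/LeoII	LeoII	LeoII	R21-E92	21	R	92	E	zeta-type bridge positionally conserved in LeoII
LeoII/LeoII	LeoII	LeoII	E8-R77	8	E	77	R	zeta-type bridge partially conserved in LeoII (K->R)
LeoII/LeoII	LeoII	LeoII	D24-R88	24	D	88	R	zeta-type bridge partially conserved in LeoII (K->R)
D14-3-3e/D14-3-3e	D14-3-3e	D14-3-3e	R19-E92	19	R	92	E	only formable bridge in the epsilon homodimer
D14-3-3e/D14-3-3e	D14-3-3e	D14-3-3e	N6-E77	6	N	77	E	zeta bridge lost: basic partner replaced by Asn
D14-3-3e/D14-3-3e	D14-3-3e	D14-3-3e	E22-Q88	22	E	88	Q	zeta bridge lost: basic partner replaced by Gln
g14-3-3/g14-3-3	g14-3-3	g14-3-3	R22-E97	22	R	97	E	giardial homodimer bridge, zeta-like interface
g14-3-3/g14-3-3	g14-3-3	g14-3-3	D9-K82	9	D	82	K	giardial homodimer bridge, zeta-like interface
g14-3-3/g14-3-3	g14-3-3	g14-3-3	E25-K93	25	E	93	K	giardial homodimer bridge, zeta-like interface
g14-3-3/LeoII	g14-3-3	LeoII	gD9-dR77	9	D	77	R	heterodimer bridge predicted formable
g14-3-3/LeoII	g14-3-3	LeoII	gE25-dR88	25	E	88	R	heterodimer bridge predicted formable
g14-3-3/LeoII	g14-3-3	LeoII	gR22-dE92	22	R	92	E	heterodimer bridge predicted formable
g14-3-3/D14-3-3e	g14-3-3	D14-3-3e	gR22-dE92	22	R	92	E	sole formable bridge of the epsilon/giardial pair
g14-3-3/D14-3-3e	g14-3-3	D14-3-3e	gD9-dE77	9	D	77	E	like-charge contact, predicted repulsive
g14-3-3/D14-3-3e	g14-3-3	D14-3-3e	gE25-dQ88	25	E	88	Q	charged-polar contact, no bridge
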