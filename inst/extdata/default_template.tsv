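# gate template: gate_id	x	y (convex polygons, CCW)
G1	2.25	3.35
G1	3.15	3.35
G1	3.15	4.25
G1	2.25	4.25
G2	3.15	1.55
G2	4.05	1.55
G2	4.05	2.45
G2	3.15	2.45
G3	0.45	2.25
G3	1.35	2.25
G3	1.35	3.15
G3	0.45	3.15
G4	2.15	0.65
G4	3.05	0.65
G4	3.05	1.55
G4	2.15	1.55
G6	1.35	2.85
G6	2.25	2.85
G6	2.25	3.75
G6	1.35	3.75
G8	0.45	0.85
G8	1.35	0.85
G8	1.35	1.75
G8	0.45	1.75
G9	1.65	1.75
G9	2.55	1.75
G9	2.55	2.65
G9	1.65	2.65
G10	2.75	2.45
G10	3.65	2.45
G10	3.65	3.35
G10	2.75	3.35
G11	3.05	0.3
G11	3.95	0.3
G11	3.95	1.2
G11	3.05	1.2
G13	0.05	3.25
G13	0.95	3.25
G13	0.95	4.15
G13	0.05	4.15
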