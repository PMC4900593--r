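row	UMMZ240023_iontorrent	UMMZ240022_iontorrent	UMMZ192977_iontorrent	UMMZ192977_454
A	4	11	6	1
C	1	5	5	3
G	0	2	2	0
T	2	12	10	2
N	8	16	6	2
insertions_added	0	5	0	0
total_bp	5406	10746	9593	15540
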