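gene	brain	heart	kidney	liver	lung
NEFL	120	2	1	0	3
MOG	85	1	0	0	1
NPPB	1	60	2	1	2
REN	0	1	45	2	1
ALB	3	4	5	400	2
SFTPC	0	1	1	0	70
GAPDH	50	48	52	49	51
CRP	2	3	2	7	2
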