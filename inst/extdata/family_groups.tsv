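family	group
ASCa	A
ASCb	A
MyoD	A
E12/E47	A
Ngn	A
NeuroD	A
Atonal	A
Mist	A
Beta3	A
Oligo	A
Net	A
Mesp	A
Twist	A
Paraxis	A
MyoRa	A
MyoRb	A
Delilah	A
Hand	A
PTFa	A
PTFb	A
SCL	A
NSCL	A
Myc	B
Mad	B
Mnt	B
Max	B
USF	B
SREBP	B
MITF	B
TF4	B
MLX	B
AP4	B
Bmx	B
Figalpha	B
Clock	C
Cycle	C
ARNT	C
Sim	C
Trh	C
HIF	C
AHR	C
Emc	D
H/E(spl)	E
Hey	E
Kn(col)	F
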