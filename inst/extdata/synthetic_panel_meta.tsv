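id	species	family	group
ASCa-1	synthetic	ASCa	A
ASCa-2	synthetic	ASCa	A
ASCa-3	synthetic	ASCa	A
ASCa-4	synthetic	ASCa	A
ASCb	synthetic	ASCb	A
MyoD	synthetic	MyoD	A
Da	synthetic	E12/E47	A
Ngn	synthetic	Ngn	A
NeuroD	synthetic	NeuroD	A
Atonal-1	synthetic	Atonal	A
Atonal-2	synthetic	Atonal	A
Atonal-3	synthetic	Atonal	A
Mist	synthetic	Mist	A
Beta3	synthetic	Beta3	A
Oligo	synthetic	Oligo	A
Net	synthetic	Net	A
Mesp	synthetic	Mesp	A
Twist	synthetic	Twist	A
Paraxis	synthetic	Paraxis	A
MyoRa	synthetic	MyoRa	A
MyoRb	synthetic	MyoRb	A
Delilah	synthetic	Delilah	A
Hand	synthetic	Hand	A
PTFa-1	synthetic	PTFa	A
PTFa-2	synthetic	PTFa	A
PTFb	synthetic	PTFb	A
SCL	synthetic	SCL	A
NSCL	synthetic	NSCL	A
Myc-1	synthetic	Myc	B
Myc-2	synthetic	Myc	B
Mad	synthetic	Mad	B
Mnt	synthetic	Mnt	B
Max	synthetic	Max	B
USF	synthetic	USF	B
SREBP	synthetic	SREBP	B
MITF	synthetic	MITF	B
TF4	synthetic	TF4	B
MLX	synthetic	MLX	B
AP4	synthetic	AP4	B
Bmx	synthetic	Bmx	B
Figalpha	synthetic	Figalpha	B
Clock	synthetic	Clock	C
Cycle	synthetic	Cycle	C
ARNT	synthetic	ARNT	C
Sim	synthetic	Sim	C
Trh	synthetic	Trh	C
HIF	synthetic	HIF	C
AHR	synthetic	AHR	C
Emc	synthetic	Emc	D
HES-1	synthetic	H/E(spl)	E
HES-2	synthetic	H/E(spl)	E
HES-3	synthetic	H/E(spl)	E
HES-4	synthetic	H/E(spl)	E
HES-5	synthetic	H/E(spl)	E
HES-6	synthetic	H/E(spl)	E
HES-7	synthetic	H/E(spl)	E
HES-8	synthetic	H/E(spl)	E
Hey	synthetic	Hey	E
Kn	synthetic	Kn(col)	F
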