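name	hemisphere	group	index
V1	L	1	1
V2	L	1	2
V3	L	1	3
V4	L	1	4
ProS	L	2	5
DVT	L	2	6
POS1	L	2	7
POS2	L	2	8
v23ab	L	2	9
VMV1	L	3	10
VMV2	L	3	11
VMV3	L	3	12
VVC	L	3	13
PHA1	L	4	14
PHA2	L	4	15
PHA3	L	4	16
Hipp	L	5	17
PreS	L	5	18
EC	L	5	19
PeEc	L	5	20
FFC	L	6	21
PIT	L	6	22
V8	L	6	23
TE1p	L	7	24
TE2p	L	7	25
TE1a	L	8	26
TE1m	L	8	27
TE2a	L	8	28
TGd	L	8	29
TGv	L	8	30
V1	R	1	31
V2	R	1	32
V3	R	1	33
V4	R	1	34
ProS	R	2	35
DVT	R	2	36
POS1	R	2	37
POS2	R	2	38
v23ab	R	2	39
VMV1	R	3	40
VMV2	R	3	41
VMV3	R	3	42
VVC	R	3	43
PHA1	R	4	44
PHA2	R	4	45
PHA3	R	4	46
Hipp	R	5	47
PreS	R	5	48
EC	R	5	49
PeEc	R	5	50
FFC	R	6	51
PIT	R	6	52
V8	R	6	53
TE1p	R	7	54
TE2p	R	7	55
TE1a	R	8	56
TE1m	R	8	57
TE2a	R	8	58
TGd	R	8	59
TGv	R	8	60
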