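# Approximate NavAb (bacterial voltage-gated sodium channel) transmembrane
# segment ranges, applied to all four chains. Residue numbering follows the
# construct of the pre-open crystal structure; ranges are indicative and
# should be adjusted to the structure at hand.
chain	res_start	res_end	segment
*	12	36	S1
*	41	66	S2
*	74	96	S3
*	99	119	S4
*	120	129	S4S5_linker
*	130	160	S5
*	161	174	P_helix
*	175	179	SF
*	180	190	P2_helix
*	191	221	S6
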