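id	sequence	register	oligomer_order	orientation	source
FtsB_Ec_cc29-63	LEAVKSAIAAQSAKNAELSARNEALSKELSDIKGG	abcdefgabcdefgabcdefgabcdefgabcdefg	4	parallel	synthetic E. coli FtsB coiled-coil segment (residues 29-63); anchor residues Q39/N43/N50, Ala patch 37/38/41/44/48, G62-G63 at their published positions, generic residues elsewhere
FtsL_Ec_cc60-94	LQAIKESRAELSKERAELSVKWAELSEQEARLGKS	abcdefgabcdefgabcdefgabcdefgabcdefg	4	parallel	synthetic E. coli FtsL coiled-coil segment (residues 60-94); anchor residues R67/R74/E88, L70/E73, W81, G92 at their published positions, generic residues elsewhere
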