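predictor	position	residue
MeMo	248	R
MeMo	250	R
MeMo	264	R
MeMo	266	R
MeMo	149	K
MeMo	207	K
MeMo	270	K
MeMo	262	K
BPB-PPMS	248	R
BPB-PPMS	250	R
BPB-PPMS	264	R
BPB-PPMS	266	R
BPB-PPMS	270	K
BPB-PPMS	271	K
BPB-PPMS	569	K
MASA	248	R
MASA	250	R
MASA	249	R
MASA	149	K
MASA	207	K
MASA	271	K
MASA	569	K
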