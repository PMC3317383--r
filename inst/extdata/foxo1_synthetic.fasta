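>NP_062713.2 synthetic stand-in for mouse FoxO1
MFPTQHSATYPSEKHDMDPSHDDITSKDWSHTLCVVAELGVTSMIKASEYKTSFSCKGDP
LLTFMSNCVRFGTRYHYSFSFSSSEFVASHQDSFLTHTIRKLLNVTEEPSGEFSPQESLI
QVFAALAEHVEQEYPKGWIASGGSGQPRKCSSRRQSVRQVSYSEWTQEEFDSSIPVGVAA
AHLSLTKTSIVIFERGHRFSNSSAGWKNSIRHEKAQINRTIGHTTDETAWDGKTRFTKVE
GKSGKAPRRRAVSMDLSNKYTKSRGRAAKKKAALQTQERSDDPSWKRKDEWNSSNTSTSS
PQVGHFSAGWSCHNSVSSGISDVYSFSHSSTKAQSVIRLDVNGSENAASSSISLSASDSS
AIWVHRAYCAGRYNNIHWGEEDTAWTVKWGQREFTMYSSALSRTLMFYMNSVSFVYTTGE
SRTISSGSSRESNLNKAYSETSDNMSTLCTRFTIVCAGLDQESLYVRLTCKDYRQSGKGS
NSRAYVTLQSGDHSTQSTCTSNLDSLVSYEKSEYCAIADKVQGLRSGATIFVKLDVSFNT
ISQMDISLAVSFSDFKSGFSSSSSLGSAKHQQQSCCSLLCITISGSISNVSSVSVEARVT
RKRISLTSEYGGHFRTNLQIPESEVDIFLEIKAVVLPPTIASRSSSMSGRAP
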