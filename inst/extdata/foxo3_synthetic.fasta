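>O43524 synthetic stand-in for human FoxO3 (FOXO3_HUMAN)
MFPTQASVTYPSEKHDMDPSPDDITSKDWSHTLCVVAEDGVTSEINASETKTSFSCKPDP
LLTFMSNCARMGTRYHFSFSFSSSEFVASHQGSFLTHTIRALLWVTEEPSGPFYPQESLI
QVPAALAEHVEQEYSEGSIASGGSGQPRKCSSRRQSVRQVSYSEWTQEEFDSSIPVGVAA
AHLSLTKTSIVIFERGHRFSNSSAGWKNSIRHEKAQINRTIGHTTDETAWDGKTRFTKVE
GKSGKAPRRRAVSMDLSNKYTKSRGRAAKKKAALQTQERSDDPSWKRKDEWNSSNTSTSS
FMVLHFSAGWSCPNSVSSGISDVYSFSHSSTKAQSLIRRDVNGSENAASSSISLSASDSS
AIWVHNSYCAGRYNVIHWGEEDTAWTVKRGQREFTMYSSALSRTLGFYMNSVSFVYTTGE
SRTISSGSSFTSNLNKAKSETSDTMSTLCTRFTIVCAGLDQESSYVRLTCKDYRQSGKGS
NSRAYVTLQSGDQSTQSTATSNQDSLVSYEKSQYCAIADKVQGLGSGATIMVKLDVPFNT
ISQMDQSLAVSFSDFKSGFSSSSSLGSAKHQQQSACSLLCITISGSISNVSSMSVYASVT
AGDIFGGISGFDSAAKDHDRVRKRISLTSEYGGHIRDNMQIPESEVDIFLEIKAVVLPPT
IASRSSSMSGRAP
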