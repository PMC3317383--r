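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
>NP_001129431.1 synthetic stand-in FoxO3 ortholog, Sus scrofa
MFPTQASVTYPSEKHIMDASPDDITSKDWSETLCVVAEMGVTSEINASETKTSFSCKPDP
YLTFMSNCARMGTRYHFVFSFSSSEFVASHQCSDLMHTPRALLWVTEEPSGPFYPQESLI
QVPAALDEHVEQEYSEGSIASGGSGQPRKCSSRRQSDRQVSYSEWTQEEFDSSIPVGVSA
FHLMLTKCSIVIAERGHRFSNSSAGWKNSIRHEPAQWNRTIGHTTDMTAWDLKTRQTKVE
GKSGKAPRRRAVSMDLSNKYTKSRGRAAKKKAALQTQARSDDPSQKRKDEWNSSNTSTSS
MMVLHFSAGWSCPNSVSSGISDVYSFSHSSTKAQSLIRRFVNGSENAASSSISLSASDSS
AIWVHNSYCQGRYNVIHWEREDTAWTVKRGQREFFMYSSALSRCLGFYMRSVSFVYTMGE
SDTISSISSFTSNLNKLKSETSDTMSTTCTVFTIVCAGRWQESSYVRLTCKDYRQSGKGS
FSRVYVTLQSGDQSTQSTATSNQDSLVSYEKSQYCAIADKVQGLGSGATIMVKLDVPFNT
ISQMDQSLAVSFSDRKSGFSSSSSLGSAKHQQQSACSLLCITISGSISNVSSMSVYASVT
AFDIFGGISGFDSFAKDHDRVRKRISNTSEYGGHIRDNMQIPESWVDIFLEIKAVVLPPT
IVSRSSSMSGCTP
>NP_001099865.1 synthetic stand-in FoxO3 ortholog, Rattus norvegicus
MFPTQASVTYISEKHDMDPSPTDITSKDWSHTLCVVAEDGVESEINASETKTSFSCKPDP
LLYFMSNCARCGPRYFFSFSFSMLEFVASHQGSFLTHTIRGLLEVTEEPSGPFYPQESLI
QVPAALAEHVEQEYSEGSIASGGSGQPRKCSSRRQSVRPVSYSEWTQEEFDSSIPTGVAA
AHLSLTKTSIVIFNRGHRFSNSSAGWKNSIRHEKAQINRTIGHDTDETAWEGKKRFTFVE
GKSGKAPRRRAVSMDCSNKYTKSRGRAAKKKAALQTQERSDDPSWKRKDEWNSSNTSTSS
FMVLHFSAGRSCPNSVSSGISDVYSFSHSSTKAQSLIRRDVNGSENAASSSSSLSASDSS
AIWVHNSFCAGRYNVIHWGEEDTAQLVKRGQREFAMYSSALSRALGFYMNSVSFVYTHGE
SRTISSGSSFTSNLNNAKSEDSDTMSTLCTRFTIVCAGLDQFSSYVRLTCKDYRQSGKGS
NSRSYVTLPSADQSTQSTATSNQDSLVSYEKSQYCAIADKVQGLGSGAHIMVKMDVPFKT
ISQMDQSLMVSFSDFKSGFSHSSSLGSAKHQQQSACSLLCITISISISNKSLMSVYASVT
AGDIAGGISGFDSAAKPHDRVRKRISGTSEYGGHIRDNMQIPESFVDIFLEIKAVVLPPT
IASRSSSMSGRAP
>NP_062714.1 synthetic stand-in FoxO3 ortholog, Mus musculus
MPPSQASVTYPSECHDMQPSPDDITSKDWSSTLCVVAHDGVTSVANASETKTSFSCKPDP
LLTFMSNCARMEGRWHFSFSFSSSEFVASHQGSFLTHTIRRLLWVTEESSGPFYPQEVLI
QVPWALAEHVEQEYSEESIAPGGSGQPRKCSSRRQSVRQVSYSEWTQEEFDSSIPVGVAA
AHLSLTDTSIVIFERGHRFSNSSAGWKNSIRHNKAQINYTIGHTTDETAWDGKTRFTKVK
GKSGKAPRRRAVSMDLSNKYTKSRGRAAKKKAALQTQERSDDPSWKRKDEWNVSNTSTSS
FMVLHFSAGWSCPNSVSSGISDQYSFSHSSTKAQSLIRRDVNGSENAASSSISLSASDSS
AIWVHISYCAGRYNVIHWGEEDTAWTVKRAQREFVMQSSQLSREVGFCMNSVSFVYTGGE
SRTISSGSSFTSNLNKAKSETSDTISTLCTRFTIFCAGLDQESSYVRLTCKDYRQSGKGS
NSRAYVTLQDWDQSTQSTATSLQDSLVSYEKSQYCAIATKVQGLGQGATIMVKLDVPFNT
IFQMDQSLAVSFSDFDSGSSSSSSLGSAKHQQQSACSLLCITISGSISNVSSMSVYASVT
AGDIFGGISGFDSAAKDHDRCRKRISLTSEYGGHIRDNWQIPESNVDIFLEIKAVVLPPT
IWSESSSMSDRAP
>XP_615634.2 synthetic stand-in FoxO3 ortholog, Bos taurus
MFPTQASGTYPSEKHDMDPSPDDITSKDWSHTLCVVAEDGVTSEINASETKTGFSCKPDP
QLTFMSNCARMGTRYHFSFSFSSDEFAVSHQGSFLTHTIRALLWVNEEPSGPFYIQESLI
QVPAALAEHVEQEYSEGSIASGGSGQPRKCSSRRQSNRQVSYSEWLQEEFDSSIPVGVAT
AHLSLTKTSIVIFERGHRFSNSSAGWKNSIRHEKAQINITIGHTTDETAWDGKDGVTKVE
GKSGKAPRRRAVSMDLSNKYTKSRGRAAKKKAALQTQERSDDPSWKRKDEMNSSNTSTSS
FMVLHFLAGWSCPNSVSSGISDVYSCSHSSTKAQSLIRRYVNGSENAASSSISLSASDSS
AIWQHNSYIFGRYNVIHWGEEDTAWTVKRGQREFMMYGSALSRWLGFYMNSVSFVYTRGE
SSTISSGSSFTSNLNKAKSYTSDYMSTLCTRPQIVCAGLDHESSYVTLTCKDYRQSYPGS
NSRAYVTLQSGDQSTQSTIDSNVDSDVSYNMSQYCAIADKVQGLGSGATIMVKPDVPFNT
ISQMDQSLAVSFSDFKSGFSSSSSLGSAKHQQQSACSLLCITISGSISNVSSMSVYASVK
AGDIFGGISGFDSAAKDHDRGRKRQSLTSENGGNIRDNMQYPESEVDIFLEIKAVALPPT
IESRSSSMSGRAP
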