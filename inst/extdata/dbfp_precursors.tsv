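name	family	cleavage_pos	sequence	note
Dbfp1_f1	Dbfp1	NA	WNDKYPGDGKDKYPGDGDDKYLGGGNDKYLGGVFDKYFGGGN	fragment; no signal peptide
Dbfp1_f2	Dbfp1	NA	KYPGDGNPKYPGGGNPKYPGGGNPKYPGGGNPKYPGGGNAKYLGGGNDKYP	fragment; no signal peptide
Dbfp2	Dbfp2	17	MLSSVTLLFVACCGMALGQGNSWDSYRPYPVYTPKPSYPDYPEKPYPPKQTYPTYPEKKYPTYPEKKYPTYPEKKYPTYPEKKYPTYPEKKYPTYPEKKYPTYPEPTYPTYTEKKYPAYTPKTYPTYTEKKYPDYPEKKYPDYPEKKYPDYPEKKYPSYPEKKYPAYPPKNSYPGRYPWRR	curated cleavage; mature 164 aa
Dbfp4	Dbfp4	16	MFGLVAVSVFLFCHSSAFSNTWQNRIKQRPTPVVPFKLEWYLGKWFTQSRQEPCSWKGSADFENMELNFVLDPKKNILYDHSIWKKNNRCVFVTFDIIPSPKTPGTFLIQDPLGDIQSGEYVILAIDPCKFVVEWGCTKPSPIGQRCDDPWVSVHTRERPSPKVLAEVDLALMRTVGVRLAELPRLSHANTPCCLGEGKLIQHDFL	curated cleavage; mature 190 aa
Dbfp5	Dbfp5	20	MFSAVTLVLLVSCCGTALSQRNSYGNYRPVKPPGQPINQYNQYSNPYRPQYNQNWNPYRPEQAPRYPQQSYPAYPPKQPYPAYPTKQPYPTDPPKQPYPANPSKPSYPANPPYDPCDEVYCRPIYCPNGQYKPTGECCPQCQPGTYLPKPWSWRGQGNVVGEQEKFVGEGNVVGDQTYDVGGQGNVVGGQRNVVDGKGNVVGEQRNNVGG	curated cleavage; mature 190 aa
Dbfp6	Dbfp6	19	MFSAASFLLLVMFCGTVTSQFYWGYLPQRLYPRDPCDDVDCRTPHCPNGGYIPIGQCCPKCKPAASWALEVTLHVFSGRPDPEYVIPRDTSAYDAILKAIGDTSTPLGERLGYNGFTVIQTHGDSEVSHWTVGWCTRPKVELRLLAAVSAMTPIGDQHPLQKEVIDTVKQSIMLCKV	curated cleavage
Dbfp7alpha	Dbfp7	15	MFFAVTLVLLVSCSGTPLGKWDPYGSSYGNSYGRPYGKAFNPYNQYGNSYPQNNQKWNSYWPNYKQPWNSYGPQQYPSYPQSGSYYPGSWGWPGNNVGSQGNAVDGLWNVVGWQGNDVDGLGNNVGKQWNDVDGVGNYVGKQWNNVD	curated cleavage; mature 132 aa
Dbfp8beta	Dbfp8	21	MKLALLAVIAFVAPSCYEATYPVPNQGRCLKDGQYFASGHFVDPTNRCTSCECFPGGNYQCRRDACPALSCPVNQRFYPHDACCQRCHGVIHSPGSASSVSSSDHDTSGTSRHTSKSSKSSRGTSKNSKSSKKSSKSKSSRKGSKGSRKGSRKGSRKGYKKYGKKGSGSSS	curated cleavage; mature 150 aa consistent with the published composition
Dbfp9beta	Dbfp9	25	MNTKQLMCLLVAAALLLASAPAANARFVYGDYDDDYGYGGKYGYPGNYGYPGNSGYPGNYGGYGNYGDNDYGGWLGGLLGGGGRGNKWGGNYGNYGYGK	curated cleavage; mature 74 aa
Dbfp10alpha	Dbfp10	19	MQSAVTLLLLVSCCGMALGQWDDYDDWDWPTGYPSYPPKQSYPPYPPYDPCKNVNCIQVVCPYGEYTPPGKCCPVCIDWGWPWGPYGSSGSDDYDDDDDYWPYNWGK	curated cleavage; mature 88 aa
Dbfp11gamma	Dbfp11	19	MCSATPFLLLVTFCGAVSSLWYPDRPCYGKVCPAIYCLYGQVTPPGKCCPQCKPDPGSNVHVPCKKDKDCAYVVCENPGEKVECHDAPSSYPPRRECHCHIPEECEKDFDCVDECGPGATCDDGACHGNDCDHT	curated cleavage; mature 115 aa
Dbfp12delta	Dbfp12	20	MALSTWSLFLIVAATMYTGSCQECPVGSILKGCEFIQGHEGPWCPVGYYCRDLMMNNLGICCRNVCWDGPPITDNYGRAIDCSRGRTGLCPGATECVRYGRYGARSFCCNIRVTIG	curated cleavage; mature 96 aa
Dbfp13alpha	Dbfp13	19	MKGVFLLLAIVCIMVEAGGRRNQRPMYRRRLPPPTTKKPPPRPTPAPTQAPRGGPYEHEQLTQNIEKQLKEMNTTLDAIYTLTNEMFTIRNKCLDAYRPSG	curated cleavage; mature 82 aa
Dbfp14gamma	Dbfp14	19	MGPNKLFVTVLILCLMGAMGGSDDPPAAPGRCYCRRVCRPNECYVGRCPRRRSWSWCCHRSHPDCEGK	curated cleavage; mature 49 aa
Dbfp15alpha	Dbfp15	18	MCLAAAVLLAIAPIANAKYGSSSDSSDSDGYNGKRGGYGRRGGLPWPRYGRGKGYGGWGDNYGAVPTYGK	curated cleavage; mature 52 aa; N-terminus completed from the intact gamma variant
Dbfp16	Dbfp16	22	MFSAVVTVLIICLMGVMGGGDREPAGPDWWCDWRWQCSRNECVVFEDFGGKFCCLWTSPLCWSKDR	curated cleavage; mature 44 aa
Dbfp17	Dbfp17	26	MTSVRILVVLMVVCILAGSVVQQAEAQCHMTLKGCANNECFTGTVGKRKKCCPKKNNACPQGLPSV	curated cleavage; mature 40 aa
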