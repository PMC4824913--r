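#NEXUS
BEGIN DATA;
DIMENSIONS NTAX=30 NCHAR=56;
FORMAT SYMBOLS="0 1 2" MISSING=?;
MATRIX
Angusaurus_spp.	1110011111 0100111011 1121100010 0010011010 1111100000 100100
Benthosuchus_sushkini	1100101101 0101110011 0110100011 0011011100 0011000000 100100
Calmasuchus_acri	0101000?00 11?1?1?102 00001?1011 111????112 0011000001 011??1
Cherninis_denwai	0101100200 1112010000 0000111011 11111111?? ?????0000? 100010
Cyclotosaurus_robustus	0101000200 1111001200 1010111111 1111111122 10???10110 002111
Edingerella_madagascariensis	010010[01]200 1111100001 00001[01]1010 10010?1101 001?011000 000100
Eocyclotosaurus_spp.	1101101201 0112111002 1110111111 10111111?2 ?????10010 122111
Eryosuchus_garjainovi	010110020[01] 111101110[01] 0000111011 1111111122 1011000101 000000
Lydekkerina_huxleyi	0110000100 0101000002 0000100001 0010001010 0011000000 000000
Mastodonsaurus_giganteus	0101001201 1101011102 1010111111 1111111122 1111000110 100011
Odenwaldia_heidelbergensis	110010020? ?1110?0??2 ????????1? ??111?11?? ?????00??? 100?1?
Paracyclotosaurus_crooshkanki	0101100200 1112010102 100?111111 11111111?? ?????1111? 11101?
Parotosuchus_orenburgensis	0100100200 1112010100 0010111011 1111111111 0011000001 100100
Procyclotosaurus_stantonensis	1101100200 111201100? 0???1??111 ?1111111?? ?????0111? 1[12]1?11
Quasicyclotosaurus_campi	0101101201 0102101002 001011?111 10??111111 10???10110 122111
Rhineceps_nyasaensis	0000000000 0001000000 0000000000 0000000100 0000000000 00010?
Tatrasuchus_wildi	0101?00200 1111000200 0000111011 1111111111 1111010111 001111
Thoosuchus_yakovlevi	1100011111 0100110012 0121100000 0010011000 1111100000 100100
Trematosaurus_brauni	1110011111 01001110?2 1121???010 01100?1020 1111100000 100100
Stanocephalosaurus_birdi	0101000200 1112011 001 0001111111 1111111111 0011011011 111001
Stanocephalosaurus_pronus	0101000200 1112011000 0001111111 1111?11111 00?1011010 111001
Uranocentrodon_senekalensis	0000000000 0000000000 0000000001 0?00000100 0000000000 000000
Vladlenosaurus_alexeyevi	1100100200 0110010010 01001?1011 1???????11 ?11?000000 100111
Watsonisuchus_spp.	0100100200 1112010010 0000111011 1011111111 0011011000 100100
Wetlugasaurus_angustifrons	010010020[01] 0111010010 0100111011 0101111111 1011000000 100100
Xenotosuchus_africanus	0101100200 1111011000 0000111011 11?1111111 0011011100 10010?
Antarctosuchus_polyodon	0?0??012?0 111201110? 10?0110111 10??1111?? ???????11? 11?101
Yuanansuchus_laticeps	0102101211 010100100? 0000111011 1?111111?? ?????1100? 2010?1
Yuanansuchus_maopingchangensis_holotype	0102101201 1101101002 0000111011 11?11111?? ?????110?? 102100
Yuanansuchus_maopingchangensis_composite	0102101201 [01]101101002 0000111011 11?11111?1 01110110?? 102100
;
END;
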