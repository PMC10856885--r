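video,condition,frame_start,frame_end,view,automatic,manual,estimated,interpolated
pair4,no_pole,2483,4746,side,1586,331,293,54
pair4,no_pole,2483,4746,top,1878,74,265,47
pair7,pole,3850,5798,side,1607,272,246,100
pair7,pole,3850,5798,top,2063,27,113,22
pair7,no_pole,750,2600,side,1285,208,287,71
pair7,no_pole,750,2600,top,1724,53,74,0
pair10,no_pole,3850,5798,side,1353,251,236,109
pair10,no_pole,3850,5798,top,1570,151,209,19
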