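scenario,mean_re_top,stdev_re_top,mean_re_side,stdev_re_side,mean_re_stereo,stdev_re_stereo
no_pole,0.47202,0.34563,0.29831,0.27472,0.61930,0.55591
pole,0.30597,0.20053,0.28490,0.18405,0.91065,0.80017
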