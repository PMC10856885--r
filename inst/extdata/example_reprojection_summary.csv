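video,condition,view,mean_re,stdev_re,total_points,points_gt_thresh
pair4,no_pole,side,3.98679,2.84289,2264,39
pair4,no_pole,top,6.49004,5.74389,2264,373
pair7,no_pole,side,2.05453,2.52104,1851,33
pair7,no_pole,top,2.66366,3.13255,1851,47
pair10,no_pole,side,2.99391,2.62791,1949,41
pair10,no_pole,top,4.08886,3.31717,1949,119
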