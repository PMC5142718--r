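# study_name: synthetic_wilcox_shape
# horizon_cycles: 24
# nonpreg_count: 10
cycle,n_start,preg_hcg,preg_clin,finished,dropped
1,221,69,58,0,1
2,162,49,44,0,1
3,117,33,30,0,0
4,87,25,20,0,1
5,66,15,15,0,1
6,50,7,7,0,1
7,42,4,3,0,1
8,38,7,6,0,1
9,31,3,2,29,0
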