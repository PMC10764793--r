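sample_id,sen_pct,spec_pct,fn_ratio_pct,fp_ratio_pct
1,98.93,97.3,1.07,2.7
2,91.5,93.5,8.5,6.5
3,88.3,93.5,11.7,6.5
4,91.5,93,8.5,7
5,91.6,95.2,8.4,4.8
6,88.7,92.8,11.3,7.2
7,87,94.1,13,5.9
8,90.5,94.1,9.5,5.9
9,90.8,93.6,9.2,6.4
10,90.2,93,9.8,7
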