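t,arf_mosf,copd_chf_cirrhosis,coma,cancer
0,0.994,0.998,0.993,0.993
30,0.691,0.889,0.630,0.578
60,0.601,0.837,0.609,0.407
90,0.562,0.800,0.581,0.264
120,0.532,0.772,0.569,0.190
150,0.508,0.751,0.551,0.135
177,0.493,0.733,0.545,0.108
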