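condition,day,onl_um,onl_cv,rpe_um,rpe_cv,height_um,height_cv,pr_um,pr_cv
acute,1,128.31,0.10,136.59,0.16,121.39,0.06,129.71,0.08
acute,3,110.90,0.22,196.09,0.23,131.55,0.08,78.07,0.18
acute,7,87.86,0.36,156.98,0.19,125.08,0.10,60.96,0.20
acute,14,94.38,0.32,146.75,0.31,123.95,0.11,64.52,0.25
acute,21,94.50,0.28,137.17,0.33,121.55,0.08,69.13,0.24
cnv,1,408.75,0.24,345.66,0.50,170.38,0.19,276.72,0.43
cnv,3,418.96,0.24,428.85,0.13,204.83,0.19,278.93,0.25
cnv,7,566.08,0.34,566.49,0.32,246.35,0.32,401.73,0.50
cnv,14,457.69,0.39,520.06,0.30,197.74,0.29,314.71,0.49
cnv,21,433.87,0.43,528.33,0.37,178.06,0.26,342.27,0.52
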