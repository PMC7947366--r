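variable,beta,se,or,ci_lower,ci_upper,p_value
p5_le_56.25,0.165,0.489,1.18,0.453,3.074,0.737
p10_le_58.1,0.919,0.506,2.51,0.93,6.758,0.065
p75_gt_76.25,0.172,0.469,1.19,0.474,2.976,0.709
p90_gt_81.9,-1.144,0.632,0.32,0.092,1.099,0.068
p95_gt_88.1,2.491,0.566,12.08,3.98,36.655,0.0009
skewness_gt_0.31,1.476,0.265,4.38,2.604,7.351,0.0009
entropy_gt_3.41,1.37,0.278,3.94,2.28,6.788,0.0009
inhomogeneity_gt_0.136,0.349,0.305,1.42,0.78,2.576,0.249
intercept,-3.518,0.467,0.03,NA,NA,0.0009
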