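feature,auc,ci_lower,ci_upper,p_value,youden,cutoff,direction,sensitivity,specificity,self_consistent
p5,0.561,0.509,0.611,0.041,0.113,56.25,less_equal,56.77,54.45,0
p10,0.549,0.498,0.600,0.092,0.102,58.1,less_equal,48.96,61.26,1
p25,0.518,0.467,0.569,0.553,0.059,67.25,less_equal,68.75,37.17,0
p50,0.525,0.469,0.571,0.503,0.086,69.5,greater,66.67,41.88,0
mean_ms,0.508,0.457,0.559,0.790,0.070,70.8,greater,68.75,38.22,0
p75,0.556,0.505,0.620,0.060,0.138,76.25,greater,69.79,43.98,1
p90,0.582,0.525,0.639,0.005,0.169,81.9,greater,79.17,37.7,1
p95,0.660,0.606,0.715,0.0009,0.403,88.1,greater,86.98,43.46,0
skewness,0.633,0.583,0.682,0.0009,0.301,0.31,greater,75,54.97,0
kurtosis,0.521,0.469,0.572,0.492,0.069,0.598,less_equal,74.48,32.46,0
entropy,0.745,0.695,0.794,0.0009,0.404,3.41,greater,76.56,63.87,1
inhomogeneity,0.681,0.632,0.727,0.0009,0.305,0.136,greater,80.21,50.26,1
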