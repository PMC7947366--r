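feature,level,responsive,unresponsive,pct_responsive,p_value
p5,>56.25,21,23,47.7,0.031
p5,<=56.25,27,19,58.7,0.031
p10,>58.1,25,26,49.1,0.040
p10,<=58.1,23,16,58.9,0.040
p25,>67.25,15,16,48.4,0.223
p25,<=67.25,33,26,55.9,0.223
p50,>69.5,32,24,57.1,0.081
p50,<=69.5,16,18,47.1,0.081
mean_ms,>70.8,33,26,55.9,0.149
mean_ms,<=70.8,15,16,48.4,0.149
p75,>76.25,34,24,58.6,0.005
p75,<=76.25,14,18,43.8,0.005
p90,>81.9,38,22,63.3,0.0009
p90,<=81.9,10,20,33.3,0.0009
p95,>88.1,42,24,63.6,0.0009
p95,<=88.1,6,18,25,0.0009
skewness,>0.31,36,19,65.5,0.0009
skewness,<=0.31,12,23,34.3,0.0009
kurtosis,>0.598,12,14,46.2,0.168
kurtosis,<=0.598,36,28,56.3,0.168
entropy,>3.41,37,15,71.2,0.0009
entropy,<=3.41,11,27,28.9,0.0009
inhomogeneity,>0.136,38,24,61.3,0.0009
inhomogeneity,<=0.136,10,18,35.7,0.0009
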