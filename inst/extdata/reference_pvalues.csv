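feature,p_value
homogeneity,0.0295
contrast,0.0000
correlation,0.0009
energy,0.1408
mean,0.0000
std,0.4762
variance,0.9625
skewness,0.3051
kurtosis,0.3477
entropy,0.0018
min,0.0018
max,0.0000
cv,0.4189
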