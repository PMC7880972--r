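parameter,auc,ci_low,ci_high,cutoff,sensitivity,specificity
volume,0.780,0.64,0.91,1289.85,0.700,0.879
mean,0.771,0.64,0.91,987.52,0.846,0.667
sd,0.733,0.60,0.88,331.63,0.769,0.667
median,0.757,0.62,0.90,914.50,0.846,0.667
p5,0.679,0.52,0.83,721.5,0.692,0.778
p95,0.736,0.59,0.83,1541.5,0.769,0.741
kurtosis,0.289,0.15,0.43,0.48,1.000,0.037
diff_entropy,0.837,0.73,0.95,1.40,0.846,0.778
diff_variance,0.807,0.69,0.93,2.05,0.846,0.667
contrast,0.793,0.67,0.92,5.29,0.846,0.704
entropy,0.821,0.71,0.94,2.33,0.846,0.704
multivariate,0.902,0.79,0.97,0.46,0.800,0.909
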