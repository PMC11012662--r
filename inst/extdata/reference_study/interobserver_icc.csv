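# Inter-observer (reproducibility) ICC per measure from the original
# validation study's first round (15 photographs x 12 observers): two-way
# ICC with 95% confidence interval and the F test of subject
# discrimination. The published Total Mean row is not stored; it is
# recomputed as the unweighted mean over the ten measures.
measure,icc,ci_low,ci_high,f_value,p_value
SHA,0.986,0.972,0.994,81.5,0.000
AHA,0.973,0.942,0.990,62.9,0.000
WHA,0.963,0.929,0.986,28.0,0.000
LWA,0.990,0.979,0.996,124.7,0.000
RWA,0.972,0.946,0.989,37.0,0.000
WAD,0.994,0.988,0.998,161.2,0.000
SA,0.976,0.951,0.991,56.8,0.000
WA,0.987,0.975,0.995,89.7,0.000
PA,0.986,0.973,0.995,77.3,0.000
TA,0.988,0.977,0.995,100,0.000
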