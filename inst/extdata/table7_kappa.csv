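method,S1,S2,S3,S5,S6,S7,S8,S9
EEGNet-LSTM,0.85,0.69,0.84,0.87,0.60,0.89,0.92,0.79
LSTM,0.70,0.54,0.84,0.45,0.43,0.69,0.86,0.54
FBCSP+NBPW,0.68,0.42,0.75,0.40,0.27,0.77,0.75,0.61
Incep-EEGNet,0.71,0.37,0.87,0.48,0.47,0.88,0.76,0.79
SCCRNN,0.77,0.38,0.75,0.54,0.47,0.76,0.78,0.70
FBSF-TSCNN,0.81,0.47,0.84,0.32,0.43,0.77,0.76,0.74
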