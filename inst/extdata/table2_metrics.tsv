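metric	fold1	fold2	fold3	fold4	fold5	average
accuracy	0.69	0.81	0.81	0.71	0.73	0.75
sensitivity	0.67	0.89	0.89	0.80	0.89	0.83
specificity	0.71	0.71	0.71	0.57	0.50	0.64
ppv	0.75	0.80	0.80	0.73	0.73	0.76
npv	0.62	0.83	0.83	0.67	0.75	0.74
auc	0.68	0.79	0.79	0.80	0.78	0.77
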