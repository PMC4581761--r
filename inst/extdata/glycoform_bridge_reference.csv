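bridge,system,median_A,occupancy_pct
D93(beta)-K104(R),dgFSH,2.79,99.8
D93(beta)-K104(R),FSH15_TAG,2.8,100.0
D93(beta)-K104(R),FSH24_TAG,2.77,99.8
K51(alpha)-D153(R),dgFSH,2.81,99.7
K51(alpha)-D153(R),FSH15_TAG,2.99,97.1
K51(alpha)-D153(R),FSH24_TAG,2.79,99.5
K91(alpha)-D150(R),dgFSH,2.68,100.0
K91(alpha)-D150(R),FSH15_TAG,2.68,100.0
K91(alpha)-D150(R),FSH24_TAG,2.98,90.6
K40(beta)-D196(R),dgFSH,2.84,96.5
K40(beta)-D196(R),FSH15_TAG,3.12,77.9
K40(beta)-D196(R),FSH24_TAG,3.71,61.9
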