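component,system,mean,sd
INT,dgFSH,7274.46,72.07
ELE,dgFSH,-13883.53,117.07
VDW,dgFSH,-1932.3,20.80
GBSOL,dgFSH,-4531.92,95.29
GBTOT,dgFSH,-13073.29,80.25
INT,FSH15_NAG,7297.21,68.66
ELE,FSH15_NAG,-13797.88,203.03
VDW,FSH15_NAG,-1913.37,30.70
GBSOL,FSH15_NAG,-4601.85,171.04
GBTOT,FSH15_NAG,-13015.89,72.16
INT,FSH24_NAG,7307.17,70.01
ELE,FSH24_NAG,-13802.93,133.97
VDW,FSH24_NAG,-1962.31,31.51
GBSOL,FSH24_NAG,-4549.6,111.06
GBTOT,FSH24_NAG,-13007.67,66.04
INT,FSH15_TAG,7701.06,62.26
ELE,FSH15_TAG,-12616.12,99.75
VDW,FSH15_TAG,-2040.92,49.93
GBSOL,FSH15_TAG,-4697.16,80.48
GBTOT,FSH15_TAG,-11653.15,77.85
INT,FSH24_TAG,8118.63,56.35
ELE,FSH24_TAG,-10945.91,130.25
VDW,FSH24_TAG,-2123.45,50.04
GBSOL,FSH24_TAG,-5284.43,119.37
GBTOT,FSH24_TAG,-10235.16,68.28
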