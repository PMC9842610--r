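dinucleotide,tilt,rise,roll,slide,twist,shift
AA,-0.08,3.18,7.0,-1.27,31.0,-0.08
AC,0.23,3.24,4.8,-1.43,32.0,0.23
AG,-0.04,3.30,8.5,-1.50,30.0,-0.04
AU,-0.06,3.24,7.1,-1.36,33.0,-0.06
CA,0.11,3.45,9.9,-1.46,31.0,0.11
CC,-0.01,3.28,8.7,-1.78,32.0,-0.01
CG,0.30,3.24,12.1,-1.89,27.0,0.30
CU,-0.04,3.30,8.5,-1.50,30.0,-0.04
GA,0.07,3.37,9.4,-1.70,32.0,0.07
GC,0.07,3.22,6.1,-1.39,35.0,0.07
GG,-0.01,3.28,8.7,-1.78,32.0,-0.01
GU,0.23,3.24,4.8,-1.43,32.0,0.23
UA,-0.02,3.26,10.7,-1.45,32.0,-0.02
UC,0.07,3.37,9.4,-1.70,32.0,0.07
UG,0.11,3.45,9.9,-1.46,31.0,0.11
UU,-0.08,3.18,7.0,-1.27,31.0,-0.08
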