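logmar,snellen
-0.3,10
-0.28,10-1
-0.26,10-2
-0.24,10-3
-0.22,10-4
-0.2,12.5
-0.18,16+4
-0.16,16+3
-0.14,16+2
-0.12,16+1
-0.1,16
-0.08,20+4
-0.06,20+3
-0.04,20+2
-0.02,20+1
0,20
0.02,20-1
0.04,20-2
0.06,20-3
0.08,20-4
0.1,25
0.12,25-1
0.14,25-2
0.16,25-3
0.18,25-4
0.2,32
0.22,40+4
0.24,40+3
0.26,40+2
0.28,40+1
0.3,40
0.32,40-1
0.34,40-2
0.36,40-3
0.38,40-4
0.4,50
0.42,63+4
0.44,63+3
0.46,63+2
0.48,63+1
0.5,63
0.52,63-1
0.54,63-2
0.56,63-3
0.58,63-4
0.6,80
0.62,100+4
0.64,100+3
0.66,100+2
0.68,100+1
0.7,100
0.72,100-1
0.74,100-2
0.76,100-3
0.78,100-4
0.8,125
0.82,160+4
0.84,160+3
0.86,160+2
0.88,160+1
0.9,160
0.92,200+4
0.94,200+3
0.96,200+2
0.98,200+1
1,200
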