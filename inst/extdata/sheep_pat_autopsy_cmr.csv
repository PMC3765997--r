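subject,quantity,autopsy_g,cmr_g
1,total,235,279
1,ventricular,195,232
1,atrial,40,47
2,total,285,302
2,ventricular,265,273
2,atrial,20,29
3,total,414,446
3,ventricular,372,401
3,atrial,42,45
4,total,298,320
4,ventricular,268,277
4,atrial,30,42
5,total,194,210
5,ventricular,172,184
5,atrial,22,26
6,total,253,267
6,ventricular,225,239
6,atrial,28,28
7,total,216,257
7,ventricular,182,207
7,atrial,34,50
8,total,286,320
8,ventricular,260,279
8,atrial,26,41
9,total,160,177
9,ventricular,140,155
9,atrial,20,23
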