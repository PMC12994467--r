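# Reported beta coefficients of the clinical development-cohort regression
# from the 12 prone leads + male/age/height/weight to the orthogonal leads
# X, Y, Z. Predictor scaling and intercepts were not reported; treat as
# scale-unknown (see table2_model()).
predictor,X,Y,Z
prone_I,-0.603,0.730,-1.413
prone_II,1.123,-1.313,0.457
prone_III,-0.121,-0.390,0.726
prone_aVR,0.238,-2.091,2.028
prone_aVL,0.365,-0.847,1.707
prone_aVF,0.045,0.374,-0.181
prone_V1,0.065,-0.119,0.709
prone_V2,0.042,0.244,-0.397
prone_V3,-0.657,-0.626,2.185
prone_V4,0.552,-0.181,-1.317
prone_V5,0.055,-0.191,1.561
prone_V6,0.513,0.860,-1.166
male,0.067,0.134,-0.143
age,-0.004,0.333,-0.581
height,0.325,-0.098,-0.237
weight,-0.394,-0.376,0.943
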