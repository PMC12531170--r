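mz	intensity
4588.6	1.475
6290.4	1.399
6305.3	1.172
7291.5	0.429
7629.0	1.312
9173.7	0.266
9807.0	1.467
9960.3	0.306
10546.5	0.150
11290.1	0.314
11700.1	0.419
12536.5	0.298
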