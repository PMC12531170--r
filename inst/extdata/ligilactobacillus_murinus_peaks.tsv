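mz	intensity
5391.9	0.873
6375.1	2.304
6820.4	1.727
7590.7	0.237
7622.5	1.606
7921.5	1.334
9009.2	0.747
9140.8	0.521
9476.4	0.237
10120.0	0.365
10259.8	0.493
10343.0	0.373
10518.6	0.339
11228.3	0.274
11653.0	0.214
12242.8	0.221
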