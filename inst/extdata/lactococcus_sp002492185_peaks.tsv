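mz	intensity
6007.4	0.481
6207.7	8.853
6567.5	5.899
7069.9	5.711
7943.2	4.430
8128.9	4.894
9179.2	3.691
10178.3	0.605
10302.7	1.655
10348.2	1.448
10460.6	1.568
10801.2	1.329
10910.4	0.539
11613.1	0.603
12304.4	0.340
12457.1	0.524
13060.4	0.176
13174.6	0.212
13358.6	0.395
13973.5	0.470
15000.9	0.471
15718.9	0.186
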