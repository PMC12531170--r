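name	formula	n_carboxyl
Propionic acid	C3H6O2	1
Lactic acid	C3H6O3	1
Butyric acid	C4H8O2	1
Pentanoic acid	C5H10O2	1
Hexanoic acid	C6H12O2	1
Octanoic acid	C8H16O2	1
Decanoic acid	C10H20O2	1
Lauric acid	C12H24O2	1
Myristic acid	C14H28O2	1
Palmitoleic acid	C16H30O2	1
Palmitic acid	C16H32O2	1
Linolenic acid	C18H30O2	1
Linoleic acid	C18H32O2	1
Oleic acid	C18H34O2	1
Stearic acid	C18H36O2	1
Arachidic acid	C20H40O2	1
Arachidonic acid	C20H32O2	1
Eicosapentaenoic acid	C20H30O2	1
Docosahexaenoic acid	C22H32O2	1
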