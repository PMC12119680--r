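tt_class,mild,moderate,severe
<30,826,224,221
30-59,265,138,302
60-89,37,36,87
>=90,23,4,24
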