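name	trivial_name
Cg2DBD-NRA	Cg2DBDgamma
Lg2DBD-NRA	Lg2DBD-NRgamma
Sme2DBD-NRA1	nhr-1
Sme2DBD-NRA2	nhr-2
Sme2DBD-NRA3a	nhr-3
Sme2DBD-NRA3b	nhr-6
Eg2DBD-NRA1	Eg2DBDg
Eg2DBD-NRA2	Eg2DBDalpha
Eg2DBD-NRA3	Eg2DBDb
Sm2DBD-NRA1	Sm2DBDgamma
Sm2DBD-NRA2	Sm2DBDalpha
Sm2DBD-NRA3	Sm2DBDbeta
Cg2DBD-NRB1	Cg2DBD-NRdelta
Lg2DBD-NRB1	Lg2DBD-NRalpha/beta
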