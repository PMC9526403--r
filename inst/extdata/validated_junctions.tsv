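upstream	downstream
cox1	trnR2
trnR2	nad1
cox3	trnG
trnG	nad6
trnP	rnl
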