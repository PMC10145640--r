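stage,total,dead,imperfect
larva,1657,0,189
nymph,2607,0,41
female,380,0,22
male,76,52,0
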