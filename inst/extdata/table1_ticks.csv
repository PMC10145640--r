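season,male,female,nymph,larva
spring,49,213,1600,300
summer,13,95,804,1058
autumn,13,67,203,299
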