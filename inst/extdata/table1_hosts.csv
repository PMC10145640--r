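season,males,females,all
spring,7,11,18
summer,11,16,27
autumn,7,5,12
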