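season,stage,total,n_hosts
spring,male,50,18
spring,female,216,18
spring,nymph,1552,18
spring,larva,304,18
summer,male,14,27
summer,female,103,27
summer,nymph,863,27
summer,larva,1184,27
autumn,male,15,12
autumn,female,61,12
autumn,nymph,148,12
autumn,larva,181,12
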