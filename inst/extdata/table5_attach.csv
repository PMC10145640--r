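season,stage,modelled_days,modelled_lower,modelled_upper,observed_days,observed_sd,abundance
spring,male,7.826,6.486,9.442,3.42,2.625,50
spring,female,10.601,9.591,11.718,5.19,2.943,216
spring,nymph,4.956,4.567,5.378,2.512,1.257,1552
spring,larva,4.586,3.977,5.263,2.717,1.059,304
summer,male,8.749,7.005,10.926,3.071,3.131,14
summer,female,9.044,8.281,9.877,4.267,2.72,103
summer,nymph,4.391,4.190,4.601,2.638,0.941,1184
summer,larva,3.40,3.207,3.605,1.933,0.784,863
autumn,male,6.084,5.17,7.16,3.10,1.882,15
autumn,female,7.665,6.90,8.515,3.992,2.18,61
autumn,nymph,4.826,4.406,5.286,2.75,1.183,148
autumn,larva,4.175,3.855,4.522,2.467,0.924,181
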