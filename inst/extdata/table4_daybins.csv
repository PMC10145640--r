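stage,day,count
male,1,14
male,2,21
male,3,12
male,4,4
male,5,7
male,6,6
male,7,5
male,8,7
male,9,1
male,10,1
male,11,1
female,1,17
female,2,55
female,3,47
female,4,46
female,5,52
female,6,47
female,7,41
female,8,31
female,9,15
female,10,18
female,11,2
female,12,2
female,13,4
female,14,2
female,15,1
nymph,1,64
nymph,2,913
nymph,3,726
nymph,4,618
nymph,5,171
nymph,6,42
nymph,7,18
nymph,8,8
nymph,9,3
larva,1,105
larva,2,732
larva,3,561
larva,4,217
larva,5,48
larva,6,6
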