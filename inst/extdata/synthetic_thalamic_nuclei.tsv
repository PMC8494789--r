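1	mediodorsal
2	ventrolateral
3	ventroposterior
4	pulvinar
5	anterior
6	lateral geniculate
7	medial geniculate
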