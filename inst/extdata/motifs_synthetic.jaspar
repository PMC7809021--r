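>GAINED_TF_synthetic
A [ 0 0 0 0 0 100 0 0 100 0 0 0 ]
C [ 0 0 0 100 100 0 100 100 0 0 0 0 ]
G [ 0 100 100 0 0 0 0 0 0 100 100 100 ]
T [ 100 0 0 0 0 0 0 0 0 0 0 0 ]
>P53LIKE_synthetic
A [ 0 0 0 0 100 0 0 0 0 0 ]
C [ 0 0 0 100 0 0 0 0 100 100 ]
G [ 100 100 100 0 0 0 100 0 0 0 ]
T [ 0 0 0 0 0 100 0 100 0 0 ]
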