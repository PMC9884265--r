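>HSE heat-shock-element consensus TCTAGAANNTTCT
A  [ 0 0 0 1 0 1 1 1 1 0 0 0 0 ]
C  [ 0 4 0 0 0 0 0 1 1 0 0 4 0 ]
G  [ 0 0 0 0 4 0 0 1 1 0 0 0 0 ]
T  [ 4 0 4 0 0 0 0 1 1 4 4 0 4 ]
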