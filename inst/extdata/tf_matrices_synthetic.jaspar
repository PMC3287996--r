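>SYN_SP1 SP1
A  [  1  0  0  0  1  0 ]
C  [  0  1  0 11  0  1 ]
G  [ 11 11 12  1 11 11 ]
T  [  0  0  0  0  0  0 ]
>SYN_HNF1 HNF1
A  [  2  0  1 13 12  0  4 10  1  1  8 10  1 ]
C  [  0  0  0  0  1  1  4  1  2  4  1  2  9 ]
G  [ 11  1  0  0  1  0  2  2  0  1  2  1  1 ]
T  [  1 13 13  1  0 13  4  1 11  8  3  1  3 ]
>SYN_NFY NFY
A  [  3  0  1 14 13  0  2 ]
C  [  1 13 13  0  0  1  8 ]
G  [ 10  0  0  0  1  0  3 ]
T  [  0  1  0  0  0 13  1 ]
>SYN_CREB CREB
A  [  1  0 11  0  1  0  1 10 ]
C  [  1  0  0 11  0  1 11  0 ]
G  [  0 11  1  0 11  0  0  1 ]
T  [ 10  1  0  1  0 11  0  1 ]
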