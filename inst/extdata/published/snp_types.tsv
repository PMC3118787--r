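type	count
A -> G	864
C -> T	1108
A -> C	255
A -> T	289
C -> G	210
G -> T	222
T -> -	40
A -> -	38
G -> -	23
C -> -	24
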