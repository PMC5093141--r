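; sp-dialect 1
; the phrase grammar before restructuring: the first phrase stored whole
NEW
t h e b i g h o u s e
t h e s m a l l h o u s e
OLD
A 1 | t h e b i g h o u s e | #A
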