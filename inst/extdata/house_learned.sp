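; sp-dialect 1
; the five-pattern grammar produced by splitting the stored phrase against
; "t h e s m a l l h o u s e"
NEW
t h e b i g h o u s e
t h e s m a l l h o u s e
OLD
B 1 | t h e | #B @ 2
C 1 | h o u s e | #C @ 2
D 1 | s m a l l | #D
D 2 | b i g | #D
E 1 | B #B D #D C #C | #E @ 2
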