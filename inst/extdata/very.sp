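; sp-dialect 1
; self-referential repetition grammar: one appearance of ri.ri1 per "very".
; ri.ri2 is a synthetic empty-body terminator that closes the recursion.
NEW
very very very
OLD
i i1 | very | #i
ri ri1 | ri #ri i #i | #ri
ri ri2 | | #ri
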