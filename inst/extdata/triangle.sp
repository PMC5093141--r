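; sp-dialect 1
; one-dimensional polygon: lines are recursive sequences of points, a
; segment is a corner followed by a line, a polygon is a recursive sequence
; of segments.  LN.ln2 (single-point line base case), CR.cr1 (corner) and
; TR.tr2 (empty-body terminator) are synthetic additions closing the
; recursion.
NEW
corner point point corner point point corner point point
OLD
LN ln1 | point LN #LN | #LN
LN ln2 | point | #LN
CR cr1 | corner | #CR
SG sg1 | CR #CR LN #LN | #SG
TR tr1 | SG #SG TR #TR | #TR
TR tr2 | | #TR
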