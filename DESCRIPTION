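Package: icmup
Title: Multiple Alignment, Compression and Grammar Induction over Symbol Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for representing and processing knowledge as
    one-dimensional patterns of atomic symbols. Builds multiple alignments of
    an incoming (New) pattern against a repository of stored (Old) patterns by
    staged heuristic search, scores alignments by information compression,
    derives compressed code patterns from alignments and re-creates original
    sequences from them ("decompression by compression"), learns pattern
    grammars without supervision under a two-part (grammar + encoding)
    description-length criterion, and compiles grammars into a localist
    pattern-assembly network whose staged excitation and lateral-inhibition
    dynamics reproduce the recognitions of the abstract engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
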