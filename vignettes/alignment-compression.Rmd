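---
title: "Multiple alignment as compression: the model behind icmup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple alignment as compression: the model behind icmup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmup)
```

`icmup` is built on a single primitive: information can be compressed by
finding full or partial matches between patterns and unifying the parts
that are the same.  This vignette describes the model the package
implements, the choices made where the underlying theory leaves the
arithmetic open, and what the packaged experiments do and do not show.

## Patterns, grammars and the alignment model

A *pattern* is an ordered array of atomic symbols; two symbols match
exactly when their names are equal, and in no other way.  Incoming
(*New*) patterns are raw sequences.  Stored (*Old*) patterns carry
service ("ID") symbols: a class label and at least one discriminator in
front, and a single `#`-boundary at the end (`D 2 | b i g | #D`).  A
*grammar* is nothing more than a repository of stored patterns with a
symbol-frequency table; identical patterns are never stored twice —
re-observation increments a frequency.

A *multiple alignment* relates one New pattern (row 0) to appearances of
stored patterns, one row per appearance.  Legality comprises:

* **order preservation** — each row's symbol positions increase strictly
  along the column order;
* **homogeneity** — all symbols in a column share one name;
* **resolving pairs** — a matched column holds exactly two symbols of
  different kinds: sensory with stored contents (recognition), stored
  contents with the service symbol it references (reference resolution),
  or a row-0 code symbol with a service symbol (decoding);
* **data-grounding** — every appearance must reach row 0, directly or
  through resolved references to grounded appearances.

The last two rules are not decorative.  Without them the compression
score below can be farmed: two references could share one service
symbol, or towers of mutually-referencing appearances could bank
unification credit for material the input never shows.  Every printed
worked alignment of the source theory satisfies both rules.

## The compression score

The theory defers exact symbol costs to its longer expositions, so the
package defines a two-mode cost model.  The default, used in all worked
examples, is uniform: every symbol costs `ceiling(log2(d))` bits, `d`
the number of distinct names in play.  The alternative charges Shannon
costs `log2(total/freq)` from the grammar's frequency table (these
satisfy the Kraft equality exactly).

An alignment is scored as

* `b_gain` — one symbol cost per unification (a two-entry column stores
  one copy instead of two);
* `b_code` — the cost of everything a stored row asserts without
  support: its unresolved service symbols (these form the residual
  *code*) and its unexpressed contents symbols;
* `cs = b_gain - b_code`.

Unmatched row-0 symbols are not charged: failing to explain input is a
missed gain, not an offence.  One asymmetry matters: a *production*
alignment — one whose row 0 is a code pattern, so that every row-0 match
is to a service symbol — necessarily leaves all terminal contents
unexpressed, because those terminals are its output.  Decoding therefore
selects, among the alignments found, the one consuming the most code
symbols, breaking ties by `cs`.

The score departs deliberately from the simpler "matched New symbols
minus code" form: under that form a single repetition wrapped in a
self-referential pattern always scores below the flat reading (the
wrapper adds service symbols while the matched input is unchanged), so
recursion could never win at depth one.  Crediting every unification —
including the resolution of references between stored patterns — makes
hierarchical readings win exactly when they bind structure together,
which is the behaviour the worked recursion example requires.

## Building alignments: staged bottom-up composition

The search is staged and heuristic: it looks for alignments that are
good enough, not provably optimal.  Stage 1 interprets every stored
pattern directly against the input (terminals may bind input positions;
for code input, a pattern's own service symbols may bind row-0 symbols;
anything may stay open).  Each later stage composes retained
interpretations into larger ones by resolving reference pairs
(`X ... #X`) with the service symbols of structures built below —
including fresh appearances of patterns already used, which is what
recursion needs.  Per (pattern, span) only the best few interpretations
survive, ranked by compression and, separately, by input coverage (the
coverage channel is what keeps production alignments alive).  The search
stops when three successive stages fail to improve the best selection.
Finally a weighted-interval dynamic programme selects the best ordered,
non-overlapping set of top-level structures, which is materialised as an
explicit alignment and rescored.

Two properties of this shape are worth noting.  First, hierarchical
scaffolding competes only within its own span: a greedy flat structure
spanning the whole input cannot crowd out the pieces of a hierarchy
whose payoff arrives only when its top pattern binds them.  (An earlier
design that grew one global alignment row by row failed on exactly this
point.)  Second, the final selection never interleaves two top-level
structures; crossing top-level readings are expressible in the alignment
formalism but were never observed to score best, and the restriction is
what keeps selection exact.

An exhaustive oracle (`enumerate_alignments_oracle`) enumerates *every*
legal alignment of tiny instances (25 symbols, bounded appearances) by
depth-first search over symbol pairings, scoring them independently of
the composition machinery.  The test suite checks that the heuristic's
best compression score equals the oracle's optimum on such instances.

## Encoding, decoding, and residual redundancy

Scanning the best alignment's columns left to right and collecting the
service symbols that nothing resolved yields the *code pattern*
(`E 1 1 2 1 #E` for the eleven-letter phrase below).  The code is
shorter than the input but deliberately not redundancy-free: fed back
into the same engine as if it were input, its residual redundancy
suffices to re-create the original sequence exactly — compression run
twice amounts to decompression.  `residual_redundancy()` reports the
raw-to-code cost ratio (11/6 for the phrase example under uniform
costs).

## Learning

Learning is unsupervised and proceeds one sequence at a time:

* an unexplained sequence is stored whole, with fresh service symbols —
  one-trial storage, so a single exposure already parses;
* an exact re-observation increments frequencies;
* a partial match against one stored pattern splits it: maximal matched
  runs (at least two symbols; shorter overlaps are treated as
  accidental) become patterns, the two sides of a gap become
  alternatives in one class (the incoming side takes the first
  discriminator), and an abstract pattern records the class sequence.
  The split source is retired — patterns are never modified, only
  created and destroyed;
* once an abstraction exists, a partially recognized sentence extends it
  instead: an open or partially matched slot whose boundaries are
  unambiguous takes the unexplained stretch as a new class member.
  Stretches spanning two adjacent open slots have no safe cut point and
  the sentence is stored whole, to be resolved when more of it is
  recognizable; this is also why, after the first abstraction forms,
  pairwise splits of stored whole sentences are suspended — they would
  found rival hierarchies with fused segment boundaries.

Grammar candidates are ranked by the two-part description length
`t_bits = g_bits + e_bits`: the cost of writing the grammar down plus
the cost of encoding the corpus with it (unencodable residue charged at
raw cost).  `induce()` maintains a small beam of candidates (default 4),
branching on each sentence between the learner's preferred action and
plain storage, scoring candidates between batches on a recent window of
the corpus, pruning patterns that no retained encoding uses (sparing
frequently re-observed ones), and scoring the full corpus once at the
end.  The learning-event log is append-only and replaying it reproduces
the grammar exactly.

## The synthetic corpus

`default_template()` fixes the study conditions for induction: three
slots — two determiners, five adjectives, five nouns (50 sentence types)
— sampled uniformly, spelled out letter by letter, 50 sentences, seeded.
Two design requirements shape it.  Diversity: with only a handful of
sentence types, storing each sentence whole genuinely *is* the better
two-part code (a three-symbol code per sentence beats a six-symbol one),
and no honest learner should prefer slot structure there.
Identifiability: every slot needs at least two alternatives, because a
slot with one constant filler is indistinguishable, on distributional
evidence, from a fixed prefix of the neighbouring class — and fusing it
gives a strictly shorter code, so demanding its recovery would ask the
learner to prefer a worse description.  Under these conditions the test
asks for exact recovery of the slot partition plus a strictly better
`t_bits` than the naive one-pattern-per-sentence grammar.

What the generator does not emulate: morphology, variable sentence
length (beyond the optional bounded-repetition slot), noise, or
ambiguity between slot boundaries inherent in real text.  Passing the
recovery test shows the restructuring operators and the two-part
criterion interlock correctly, not that the learner segments arbitrary
natural language.

## The neural realization

`compile_graph()` turns a grammar into a localist network: one *pattern
assembly* per stored pattern, one neural-symbol node per symbol
occurrence, a receptor node per terminal name, directed excitatory edges
from every receptor or service node to every other same-named node (the
labeled-line principle), and lateral links between neighbours within an
assembly.

`simulate_recognition()` is a discrete staged process.  Receptor nodes
for the input are clamped on; each stage, assemblies bind available
signals to their contents nodes in order (a reference pair must bind
both its halves to one and the same source assembly); an assembly fires
when a sufficient fraction of its contents is driven (`theta`, default
0.4 — an innermost appearance of a self-referential pattern can never
bind more than half its contents, so a threshold above 0.5 would forbid
recursion outright) and when it wins the local competition: per
(assembly, span) only the few most *valuable* bindings fire, where a
binding's value is what its whole support consumes minus what it leaves
dangling — the network counterpart of the compression score.  Bindings
whose support would consume any signal twice are suppressed outright,
the network form of the resolving-pair rule.  Fired assemblies pass
their service symbols onward with strength proportional to how fully
they are driven, so quality propagates and partial readings decay up the
hierarchy.  Bodyless terminator patterns stand as single position-free
virtual copies.  Lateral inhibition within a fired assembly suppresses
its uniformly active body and leaves the boundary service nodes
untouched — run-length encoding in neural form (`apply_inhibition()` is
exposed and tested separately).

The winning structure — the network's analog of a multiple alignment —
is read out greedily: the instance explaining the most unexplained input
wins, ties broken by support value, and its whole support is pulled in;
signal exclusivity holds across picks.  On the phrase grammar and on the
self-referential repetition grammar (one to five repetitions) the
winning multiset equals the abstract engine's appearance multiset
exactly, which is the equivalence the package tests.  On the
doubly-recursive polygon fixture the simulation converges to the right
corner/segment/polygon structure but can retain one spurious
single-point-line reading; exact agreement there would require giving
the network the abstract engine's global search, which would defeat the
point of comparing two routes.  This is a known limitation, stated here
deliberately.

`estimate_capacity()` implements the order-of-magnitude bookkeeping that
connects the architecture to brain-scale numbers: neuron-count range
times bits per neuron in binary megabytes, rounded to one significant
figure (1000–10000 MB), scaled by an assumed threefold compression
(3000–30000 MB), against a knowledge estimate from a compressed
reference corpus (1300 MB, i.e. roughly 4000 MB uncompressed) stored in
triplicate (12000 MB) — which lands inside the range.

## Numerical choices and degenerate inputs

* Uniform costs use `max(1, ceiling(log2(d)))` so a one-symbol alphabet
  still has positive cost.
* Alignment ties on `cs` break toward more matched input, then smaller
  total row span (compact nestings beat stretched ones), then
  lexicographically by the derived code — full determinism for tests.
* Column order is the deterministic topological order of the column
  constraint graph (ties resolved by smallest row/position).
* The composition beams keep 5 interpretations per (pattern, span) in
  each channel; the within-pattern dynamic programme keeps 4 partials
  per state; skipped terminals are capped at 6 per appearance.  Problem
  sizes throughout the packaged experiments: phrases of 11–14 letters,
  grammars of up to ~15 patterns, corpora of 50 sentences — chosen as
  the smallest sizes at which every claimed behaviour is visible.
* The appearance cap (default 10 per pattern per alignment) bounds
  runaway recursion on self-referential grammars; the recursion fixtures
  need depth equal to the repetition count only.
* Degenerate inputs: an empty grammar yields exactly the single-row
  alignment; an empty code or a code matching nothing raises a typed
  decode failure; sensory symbols outside the receptor alphabet are an
  error; a bodyless pattern is legal and acts as a recursion terminator.

## Open choices resolved here

Where the source theory is silent, the package commits as follows: the
dialect uses explicit `|` delimiters (undelimited lines fall back to a
warning heuristic); discriminators are reused across classes by default,
with `unique_ids = TRUE` available to remove decode ambiguity between
classes that share discriminator names; probability outputs are omitted
rather than guessed (frequencies are kept and drive the optional
frequency cost model); learning from code patterns and intermediate
abstraction levels are out of scope; and the recursion fixtures carry
explicitly synthetic base-case patterns (an empty-body terminator for
the repetition grammar; a corner, a one-point line and a terminator for
the polygon grammar), since the recursive definitions as printed have no
base cases.
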