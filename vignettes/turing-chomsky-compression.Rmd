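---
title: "Scoring syntactic derivations by compressibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring syntactic derivations by compressibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcc)
```

## The idea

Minimalist syntax builds sentences by MERGE: a binary set-forming operation
that either introduces a new lexical item (`{Z, {X, Y}}`, external merge) or
re-merges a piece of existing structure at the root (`{X, {X, Y}}`, internal
merge, leaving a silent lower copy — movement). At many points a derivation
faces a choice between options that are equally expressive: extend the
structure at the root or insert material counter-cyclically; move the higher
or the lower of two wh-phrases; raise a subject or leave it in situ.
Grammars systematically license one option and exclude the other, and the
classical economy conditions of syntactic theory (No Tampering, Relativised
Minimality, Resource Restriction, minimal search) describe the licensed
choices case by case.

This package implements a single quantitative criterion that subsumes these
case-by-case conditions in the worked examples it ships: encode the
derivational object each option gives rise to as a short symbol sequence,
estimate the Kolmogorov complexity of each sequence with the Lempel–Ziv
(1976) parsing, and predict that **the option whose encoding attains the
lower normalized complexity is the grammatically licensed one** (the
Turing–Chomsky Compression principle). True Kolmogorov complexity is not
computable; the LZ76 phrase count is the standard effective upper-bound
proxy, computable by a one-pass copy-and-insert parser.

## The estimator

`lz76_phrase_count()` scans a sequence left to right and closes a phrase
each time it meets a substring of consecutive symbols not seen anywhere in
the preceding text (self-overlap allowed). Two conventions matter on short
sequences and are fixed package-wide:

* **End of string.** The final phrase counts even if it is still copyable
  when the input ends (the exhaustive-history convention). Published
  variants differ here; `0 0 0 0` parses to 2 phrases (`0 | 000`) and the
  phase/non-phase alternation `0 1 0 1 0 1` to 3 (`0 | 1 | 0101`), the
  maximally compressible pattern a cyclic C–T–v–V derivation emits.
* **Normalization.** The shipped default is the Kaspar–Schuster
  normalization `C = c · log2(n) / n` (`ks_log2`), the phrase count
  relative to the asymptotic count of an incompressible sequence. On the
  very short sequences derivational encodings produce, `C` is an unstable
  estimator (the package warns below 10 symbols) and takes values roughly
  1–2.5; values are meaningful only under a fixed encoding convention, and
  every `complexity_result` records its scheme id.

A brute-force oracle (`brute_force_phrase_oracle()`, explicit history
enumeration, capped at length 12) verifies the fast parser; the test suite
checks equality exhaustively over all binary strings to length 9 and
ternary strings to length 7, and on 10,000 seeded random strings.

## Encoders: what gets compressed

Four serializers produce the scored sequences, one per empirical domain:

* `encode_node_terminal()` — top-down (pre-order, left before right)
  enumeration of branch labels and terminal categories. Used for the
  adjunction contrast: extending `[a [b] [g [d] [e]]]` at the root with a
  new element gives the sequence `a l a b g d e`, counter-cyclic insertion
  inside the lowest set gives `a b g d e e l`.
* `encode_search_path()` — the node steps a probe's search traverses from
  its sister down to the goal, the sequence beginning at the probe's
  maximal projection.
* `encode_movement_path()` — one symbol per occurrence site of a movement
  chain, base first, each site represented by the label of its immediately
  dominating node.
* `encode_label_sequence()` — the successive phrase labels of the
  structure left to right (the category of each terminal-level phrase
  unit), used for the raising/labeling contrast.

Copies default to `same_symbol_as_antecedent`: a copy is the same object
as its antecedent, so it contributes its antecedent's symbol. That single
decision is what makes the raised structure the more compressible one in
the labeling contrast — the lower copies repeat the subject's `D` symbol,
and repetitions are what the LZ76 parser copies instead of inserting.

## Calibration: pinning an under-determined convention

The reference implementation behind the published complexity values for
these contrasts prints no normalization formula, and for the node/terminal
serialization no pure function of phrase count, length and alphabet size
can separate the adjunction pair at all — both members have identical
`(c, n, α)` as plain symbol sequences. The package therefore treats the
normalization and the per-mode encoder options as a small, fully
documented grid (`normalization_schemes()` × binarization × symbol/step
policies) and ships the member that minimizes the total absolute residual
against the eight published values, with configurations that fail any
grammatical-below-ungrammatical ordering ranked below all that reproduce
the orderings:

```{r calibration}
cal <- calibrate_scheme()
cal
```

The winner is `ks_log2` with plain symbol sequences everywhere except the
node/terminal mode, which is recoded to minimal-width binary numerals
before parsing (the binary recoding is what breaks the adjunction pair's
tie, and LZ76 is natively a binary-string formulation). Three of the
eight published values are matched at printed precision (the grammatical
search path, the grammatical movement path, and the in-situ label
sequence); the remaining residuals are documented above rather than
absorbed, and the four orderings — which are the principle's actual
prediction — all hold strictly. `tcc_compare()` and the fixture runner use
this calibrated default throughout.

## Counting conventions for the integer geometry

Printed step counts fix the node-counting convention exactly once,
package-wide:

* **Transliteration.** The shipped fixtures transliterate the printed
  structures into one canonical dialect (`[Label child child]`,
  `[Cat form +F]`, `[<Cat>#i]` for lower copies). The tree model is
  strictly binary, so unary projections in printed originals are
  collapsed; silent heads (`[T]`, `[C]`) are real leaves and count as
  nodes; bar levels count as nodes.
* **Steps.** `search_depth()` counts every node on the path from the
  probe's *sister* (inclusive) down to the goal (inclusive); the probe's
  own projections are not counted. Under this one convention the polar
  interrogative yields 3 steps to the matrix verb versus 4 into the
  relative clause, and the wh-extraction pair yields depths 11 versus 9 —
  all four printed counts, with no per-example adjustment. The
  neighbouring conventions remain available as flags
  (`count_goal`, `count_domain_root`) for sensitivity analysis.

## Economy conditions as independent evidence

The checkers report violations alongside, not folded into, the complexity
verdict, since the conditions are treated as separate but interacting
factors:

* `check_no_tampering()` — every set built earlier must occur
  node-identically later; root extension passes, counter-cyclic insertion
  fails with a witness address.
* `rm_check()` — an intervener blocks a probe–goal relation when its
  features are a superset of both the probe's sought features and the
  goal's own features. The superset is taken over the *goal's* features:
  a featurally richer intervener blocks a poorer mover, a poorer
  intervener does not block a richer one, and enriching an intervener can
  never unblock (monotonicity, property-tested).
* `check_resource_restriction()` — a MERGE step may increase the number
  of accessible elements by at most one. The count treats the lexicon as
  a standing resource: an item's first use does not in itself enlarge the
  pool, so external merge of a fresh item and internal merge both come
  out at +1 (as they must, being the two legal operations), while
  hypothetical workspace-duplication steps are flagged. Lower copies are
  the same object as their antecedent and never add to the count.
* `workspace_size()` — accessible terms plus syntactic objects. Whether
  the root object counts among the terms as well as among the objects is
  genuinely unsettled in the theoretical literature; both conventions are
  implemented (`count_root_as_term`), defaulting to counting it in both.
* `markov_check()` — Resource Restriction makes derivations strictly
  Markovian; for histories ending in equal workspaces the sets of legal
  continuations coincide. `enumerate_merge_closure()` verifies the
  restriction exhaustively (a 3-item lexicon to 6 steps in the tests) and
  exposes the combinatorial explosion that motivates it: under lexical
  reuse the closure from two elements grows without bound, reaching
  millions of distinct sets within eight steps at full scale (the
  function supports that regime behind a workspace cap with an explicit
  truncation flag; the tests run the smaller regimes).

## The Bulgarian ordering data

`predict_wh_order()` derives the multiple-wh-fronting pattern from the
same primitives: minimal search from interrogative C selects the least
embedded wh-phrase as the first mover (a lower wh moving first crosses a
featurally equal intervener and is blocked by Relativised Minimality);
wh-phrases left in situ keep an unchecked focus feature; and the
remaining movers front in any order exactly when their movement-path
encodings have equal complexity — which they do, making both relative
orders of the two later movers licensed while the two-wh clauses admit
exactly one order.

```{r bulgarian}
predict_wh_order(tcc_fixture("ex12"))
```

## What the fixtures do and do not show

The fixture structures are schematic: lexical content is irrelevant to
path lengths and label sequences and is carried only for readability
(the Bulgarian clauses use category-and-feature skeletons; the raising
pair chunks `seems to be likely` as a single verbal unit, as in the
printed schematic representation). Passing tests therefore show that the
implementation reproduces the published analyses *under the shipped
transliterations and the calibrated conventions* — they do not show that
the compression criterion generalizes to arbitrary corpora, to languages
outside the worked examples, or to encodings other than the four
serializers. Phase-based opacity (the Phase Impenetrability Condition) is
deliberately not operationalized: all subterms are accessible to search,
which is an explicit extension point. Agree-style feature valuation,
head movement, linearization and semantic composition are out of scope.

## Numerical choices

Problem sizes in the tests are chosen to keep the full suite at desk
scale: 1,000 random round-trip trees, 200 random derivations, exhaustive
closure to 6 steps from 3 items, exhaustive oracle equality to length 9
(binary) and 7 (ternary) plus 10,000 random strings. All randomness is
seeded; the package itself has no stochastic component, and all grid
iteration orders in the calibration are fixed, with exact ties broken by
scheme-id order. Complexity ties in `tcc_compare()` are exact
(`1e-12`-level) ties of the normalized value, and jointly license all
minimizers — permuting candidate order never changes a report.
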