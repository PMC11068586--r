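# tcc: Turing–Chomsky Compression for minimalist syntactic derivations

`tcc` is an R toolkit for a quantitative question in theoretical syntax and
computational cognitive science: when a derivation faces two ways of
operating on its workspace — extend at the root or insert counter-cyclically,
move the higher or the lower wh-phrase, raise a subject or leave it in
situ — can the grammatically licensed option be predicted from the
*algorithmic compressibility* of what each option builds?

The package is written for linguists and cognitive scientists who work with
minimalist bare phrase structure. It provides:

* a tree model for binary-branching labeled structures with copy-indexed
  traces, read and written in labeled bracket notation
  (`parse_bracketed()`, `write_bracketed()`), with the structural
  primitives (dominance, c-command, depth, addresses);
* a MERGE engine over workspaces (`merge_external()`, `merge_internal()`)
  with the economy-condition checkers: No Tampering, Resource Restriction,
  Relativised Minimality, minimal search, and the Markov property of
  derivations (`check_no_tampering()`, `check_resource_restriction()`,
  `rm_check()`, `minimal_search()`, `markov_check()`);
* four serializers from derivational objects to finite-alphabet symbol
  sequences (node/terminal enumerations, search paths, movement paths,
  phrase-label sequences);
* a Lempel–Ziv (1976) phrase-counting estimator of Kolmogorov complexity
  with a calibrated normalization and a brute-force verification oracle;
* the comparator implementing the licensing principle, plus shipped
  worked-example fixtures (adjunction, wh-islands, polar interrogatives,
  Bulgarian multiple wh-fronting, raising/labeling) and a
  `predict_wh_order()` front end for multiple-wh ordering data.

## The principle

For a sequence $S = s_1 s_2 \dots s_n$, the LZ76 parser counts the number
$c$ of distinct phrases in the exhaustive left-to-right parsing (a new
phrase closes whenever the scanner meets a substring not seen before);
the shipped normalization is the Kaspar–Schuster form

$$C(S) \;=\; \frac{c \,\log_2 n}{n},$$

an effective upper-bound proxy for the (uncomputable) Kolmogorov
complexity $K(S) = \min\{|p| : M(p) = S\}$. Given two candidate
operations on the same workspace, each candidate's resulting structure is
serialized and scored, and the candidate attaining the **lower**
normalized complexity is predicted to be the licensed one; exact ties are
jointly licensed (which is what the Bulgarian three-wh data require).

## A worked example

The object-extraction question *"What did you persuade who to sell?"* is
ungrammatical; its counterpart *"Who did you persuade to sell what?"* is
fine. Both structures ship as fixtures with the wh-chain marked by copy
index; comparing the encodings of the two movement paths:

```r
library(tcc)
run_fixture("ex9_movement")$report
#> <tcc_report mode=movement_path scheme=ks_log2>
#>    id phrase_count length alphabet_size normalized    annotation
#>  ex9b            3      4             3        1.5   grammatical
#>  ex9a            4      4             4        2.0 ungrammatical
#> licensed: ex9b
```

Each movement path has four sites (base, two intermediate landing sites,
the specifier of CP), one symbol per site. The licensed structure's path
revisits a `VP` site, so its four-symbol sequence parses into 3 phrases
(normalized complexity 1.5); the blocked structure's path visits four
distinct site types and parses into 4 phrases (2.0). Lower complexity,
licensed — and the same comparison at the tree-geometric level gives
search depths 9 versus 11 nodes (`search_depth()`).

Minimal search itself is exposed directly. In the polar interrogative
*"Do poems that rhyme evaporate?"*, the interrogative C finds the matrix
verb in three node steps, not the relative-clause verb in four:

```r
t6 <- tcc_fixture("ex6b")
pr <- probe(find_leaves(t6, function(x) x$category == "C")[[1]], "V")
minimal_search(t6, pr)$steps
#> [1] 3
```

And the ordering front end reproduces the Bulgarian multiple-fronting
pattern (indirect object before direct object; in-situ wh blocked):

```r
predict_wh_order(tcc_fixture("ex11"))
#>                  order fronted licensed                          reason
#> 1           kogo<kakvo       2     TRUE      first mover least embedded
#> 2           kakvo<kogo       2    FALSE minimal search selects `kogo` ...
#> 3 kogo (kakvo in situ)       1    FALSE unchecked focus feature ...
#> 4 kakvo (kogo in situ)       1    FALSE unchecked focus feature ...
```

Because the published normalization for these short sequences is not fully
specified, the package pins its defaults by a documented grid search
(`calibrate_scheme()`); the calibration report shows, per contrast pair,
the fitted values, residuals against the published values, and whether the
grammatical-below-ungrammatical ordering is reproduced. See the vignette
(`vignettes/turing-chomsky-compression.Rmd`) for the model, the encoding
conventions, and the known limitations.

A thin command-line front end is installed with the package
(`system.file("cli", "tcc", package = "tcc")`) with subcommands
`complexity`, `compare`, `fixtures`, `calibrate` and `enumerate`.

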