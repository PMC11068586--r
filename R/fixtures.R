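# Worked-example fixtures: labeled-bracket transliterations of the printed
# structures, in the package's canonical dialect. Single lower-case letters
# transliterate Greek workspace labels (a=alpha, b=beta, g=gamma, d=delta,
# e=epsilon, l=lambda). Unary projections in the printed originals are
# collapsed (the tree model is strictly binary); silent heads are leaves
# with null form.

fixture_strings <- function() {
  list(
    # Adjunction and No Tampering: (2a) extended at the root by lambda (2b),
    # versus counter-cyclic insertion of lambda inside epsilon (2c).
    ex2a = "[a [b] [g [d] [e]]]",
    ex2b = "[a [l] [a [b] [g [d] [e]]]]",
    ex2c = "[a [b] [g [d] [e [e] [l]]]]",

    # Relativised Minimality: extraction of a featurally poorer adjunct
    # across a richer wh-phrase (3a, blocked) versus the converse (3b).
    ex3a = paste0("[CP [AdvP how +Q]#1 [C' [C do +Q] [TP [DP you] [T' [T] ",
                  "[VP [V wonder] [CP [DP which_game +Q +N] [C' [C +Q] ",
                  "[TP [DP PRO] [T' [T to] [VP [V play] [<AdvP>#1]]]]]]]]]]]"),
    ex3b = paste0("[CP [DP which_game +Q +N]#1 [C' [C do +Q] [TP [DP you] [T' [T] ",
                  "[VP [V wonder] [CP [AdvP how +Q] [C' [C +Q] ",
                  "[TP [DP PRO] [T' [T to] [VP [V play] [<DP>#1]]]]]]]]]]]"),

    # Structural distance: polar interrogative with a subject relative
    # clause; the matrix verb is less embedded than the relative-clause
    # predicate.
    ex6b = paste0("[CP [C Do +Q] [TP [DP [DP poems] [CP [C that] [TP rhyme +V]]] ",
                  "[T' [T] [V evaporate +V]]]]"),

    # Wh-extraction of the deeper object (9a, blocked) versus the higher
    # argument (9b, licensed); <DP> marks the movement path.
    ex9a = paste0("[CP [DP what +Q]#1 [C' [C did +Q] [TP [DP you] [T' [T pres] ",
                  "[VP [<DP>#1] [V' [V persuade] [CP [C] [TP [<DP>#1] [T' [T] ",
                  "[VP [DP who +Q] [PP [P to] [V' [V sell] [<DP>#1]]]]]]]]]]]]]"),
    ex9b = paste0("[CP [DP who +Q]#1 [C' [C did +Q] [TP [DP you] [T' [T pres] ",
                  "[VP [<DP>#1] [V' [V persuade] [CP [C] [TP [<DP>#1] [T' [T] ",
                  "[VP [<DP>#1] [PP [P to] [V' [V sell] [DP what +Q]]]]]]]]]]]]]"),

    # Labeling: raising with the subject left in situ (13a, blocked) versus
    # raised to the root (13b, licensed); terminal-level phrase units are
    # schematic chunks, as in the printed representation.
    ex13a = paste0("[g [V seems_to_be_likely] [a [D the_student]#1 ",
                   "[P' [P to] [V' [<D>#1] [V understand_the_theory]]]]]"),
    ex13b = paste0("[d [D the_student]#1 [g [V seems_to_be_likely] ",
                   "[a [<D>#1] [P' [P to] [V' [<D>#1] [V understand_the_theory]]]]]]"),

    # Bulgarian multiple wh-fronting, pre-movement clause structures.
    # (10) subject + object; (11) indirect + direct object; (12) all three.
    ex10 = paste0("[CP [C +Q] [TP [DP koj +Q +Foc] [T' [T e_vidjal] ",
                  "[VP [V] [DP kogo +Q +Foc]]]]]"),
    ex11 = paste0("[CP [C +Q] [TP [DP Ivan] [T' [T e_pital] ",
                  "[VP [DP kogo +Q +Foc] [V' [V] [DP kakvo +Q +Foc]]]]]]"),
    ex12 = paste0("[CP [C +Q] [TP [DP koj +Q +Foc] [T' [T e_pital] ",
                  "[VP [DP kogo +Q +Foc] [V' [V] [DP kakvo +Q +Foc]]]]]]")
  )
}

#' Worked-example fixtures
#'
#' Canonical transliterations of the worked examples discussed in the
#' package vignette: the adjunction/No-Tampering pair (`ex2a`-`ex2c`), the
#' Relativised Minimality pair (`ex3a`/`ex3b`), the polar interrogative
#' with a relative clause (`ex6b`), the wh-extraction pair
#' (`ex9a`/`ex9b`), the raising/labeling pair (`ex13a`/`ex13b`), and the
#' Bulgarian multiple-wh clauses (`ex10`-`ex12`).
#'
#' @param name Fixture name; see [tcc_fixture_names()].
#' @return `tcc_fixture()`: a parsed `syntactic_object`;
#'   `tcc_fixture_string()`: its labeled-bracket source;
#'   `tcc_fixture_names()`: available names.
#' @export
tcc_fixture <- function(name) {
  parse_bracketed(tcc_fixture_string(name))
}

#' @rdname tcc_fixture
#' @export
tcc_fixture_string <- function(name) {
  strs <- fixture_strings()
  if (!name %in% names(strs))
    stop("unknown fixture: ", name, "; see tcc_fixture_names()", call. = FALSE)
  strs[[name]]
}

#' @rdname tcc_fixture
#' @export
tcc_fixture_names <- function() names(fixture_strings())

## ---------------------------------------------------------------------------
## Fixture-derived probes, paths and calibration pairs
## ---------------------------------------------------------------------------

address_of_leaf <- function(t, pred) {
  hits <- find_leaves(t, pred)
  if (!length(hits)) stop("no matching leaf in fixture", call. = FALSE)
  hits[[1L]]
}

deepest_copy <- function(t, idx) {
  sites <- movement_path(t, idx)
  sites[[1L]]
}

# The four printed contrasts, grammatical member first, with closures that
# re-encode the fixture structures under an arbitrary encoder configuration.
# These are the calibration inputs and the acceptance-pipeline inputs.

#' Printed calibration targets
#'
#' The four worked-example contrast pairs and their printed normalized
#' complexity values, grammatical member first, each with an encoding
#' closure used by [calibrate_scheme()] to re-derive the symbol sequences
#' from the fixture structures under any candidate encoder configuration.
#'
#' @return List of calibration pairs (`mode`, `labels`, `targets`,
#'   `encode`).
#' @export
tcc_printed_targets <- function() {
  t2b <- tcc_fixture("ex2b"); t2c <- tcc_fixture("ex2c")
  t6 <- tcc_fixture("ex6b")
  t9a <- tcc_fixture("ex9a"); t9b <- tcc_fixture("ex9b")
  t13a <- tcc_fixture("ex13a"); t13b <- tcc_fixture("ex13b")

  c_probe6 <- probe(address_of_leaf(t6, function(x) x$category == "C"), "V")
  v_goal <- address_of_leaf(t6, function(x) identical(x$form, "evaporate"))
  tp_goal <- address_of_leaf(t6, function(x) identical(x$form, "rhyme"))

  list(
    list(mode = "node_terminal",
         labels = c("ex2b", "ex2c"), targets = c(1.88, 1.99),
         encode = function(cfg) list(encode_node_terminal(t2b, cfg),
                                     encode_node_terminal(t2c, cfg))),
    list(mode = "search_path",
         labels = c("ex6b_CV", "ex6b_CTP"), targets = c(1.72, 2.01),
         encode = function(cfg) list(
           encode_search_path(minimal_search(t6, c_probe6), cfg),
           encode_search_path(search_to(t6, c_probe6, tp_goal), cfg))),
    list(mode = "movement_path",
         labels = c("ex9b", "ex9a"), targets = c(1.50, 2.15),
         encode = function(cfg) list(
           encode_movement_path(movement_path(t9b, 1L), t9b, cfg),
           encode_movement_path(movement_path(t9a, 1L), t9a, cfg))),
    list(mode = "label_sequence",
         labels = c("ex13b", "ex13a"), targets = c(1.66, 1.86),
         encode = function(cfg) list(encode_label_sequence(t13b, cfg),
                                     encode_label_sequence(t13a, cfg)))
  )
}
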