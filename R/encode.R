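# Serializers from structures / search results / movement paths to the
# finite-alphabet symbol sequences scored by the complexity estimator.

#' Symbol sequences
#'
#' @param symbols Character vector over a finite alphabet.
#' @param provenance Optional string recording which encoder and source
#'   produced the sequence.
#' @return A `symbol_sequence` with fields `symbols`, `alphabet`,
#'   `provenance`.
#' @export
symbol_sequence <- function(symbols, provenance = NULL) {
  symbols <- as.character(symbols)
  if (length(symbols) < 1L) stop("empty symbol sequence", call. = FALSE)
  structure(list(symbols = symbols, alphabet = unique(symbols),
                 provenance = provenance),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence n=%d alphabet=%d%s>\n  %s\n",
              length(x$symbols), length(x$alphabet),
              if (is.null(x$provenance)) "" else paste0(" ", x$provenance),
              paste(x$symbols, collapse = " ")))
  invisible(x)
}

#' @export
format.symbol_sequence <- function(x, ...) paste(x$symbols, collapse = " ")

#' Encoding configuration
#'
#' Options controlling how a derivational object is serialized. The shipped
#' defaults per mode are the calibration winners (see [calibrate_scheme()]
#' and [tcc_default_config()]).
#'
#' @param mode One of `"node_terminal"`, `"search_path"`, `"movement_path"`,
#'   `"label_sequence"`.
#' @param symbol_policy `"per_distinct_label"` uses node labels as printed
#'   (bar levels and phrasal status distinguished); `"per_category"` maps
#'   each label to its base category (`T'`, `TP` and `T` coincide).
#' @param copy_policy `"same_symbol_as_antecedent"` renders a lower copy
#'   with its antecedent's symbol; `"distinct_symbol"` marks it as a trace
#'   symbol of its own; `"invisible"` omits it.
#' @param step_symbols For search paths: `"nodes"` emits one symbol per
#'   traversed node; `"transitions"` emits one symbol per endpoint of each
#'   search step, so interior nodes (left and re-entered) appear twice.
#' @param include_origin For search paths: prepend the probe's maximal
#'   projection as the search origin symbol.
#' @param binarize Binary recoding applied before complexity estimation:
#'   `"none"`, `"fixed"`/`"fixed1"` (fixed-width codes of the 0-/1-based
#'   alphabet indices in order of first appearance), or
#'   `"minwidth"`/`"minwidth1"` (minimal-width binary numerals of the same
#'   indices).
#' @return An `encoding_config`.
#' @export
encoding_config <- function(mode = c("node_terminal", "search_path",
                                     "movement_path", "label_sequence"),
                            symbol_policy = c("per_distinct_label",
                                              "per_category"),
                            copy_policy = c("same_symbol_as_antecedent",
                                            "distinct_symbol", "invisible"),
                            step_symbols = c("nodes", "transitions"),
                            include_origin = TRUE,
                            binarize = c("none", "fixed", "fixed1",
                                         "minwidth", "minwidth1")) {
  structure(list(mode = match.arg(mode),
                 symbol_policy = match.arg(symbol_policy),
                 copy_policy = match.arg(copy_policy),
                 step_symbols = match.arg(step_symbols),
                 include_origin = isTRUE(include_origin),
                 binarize = match.arg(binarize)),
            class = "encoding_config")
}

#' Calibrated default configuration per encoder mode
#'
#' The per-mode encoder settings selected by the calibration grid (see
#' [calibrate_scheme()]); used throughout the fixture comparisons and by
#' the acceptance pipeline.
#'
#' @param mode Encoder mode.
#' @return An `encoding_config`.
#' @export
tcc_default_config <- function(mode = c("node_terminal", "search_path",
                                        "movement_path", "label_sequence")) {
  mode <- match.arg(mode)
  switch(mode,
    node_terminal = encoding_config("node_terminal", binarize = "minwidth"),
    search_path = encoding_config("search_path", step_symbols = "transitions"),
    movement_path = encoding_config("movement_path"),
    label_sequence = encoding_config("label_sequence",
                                     symbol_policy = "per_category"))
}

apply_policy <- function(symbols, policy) {
  if (policy == "per_category") base_category(symbols) else symbols
}

leaf_symbol <- function(x, config) {
  sym <- x$category
  if (x$lower) {
    if (config$copy_policy == "distinct_symbol") sym <- paste0("<", sym, ">")
    else if (config$copy_policy == "invisible") sym <- NA_character_
  }
  sym
}

#' Top-down node-and-terminal serialization
#'
#' Searches the structure from top to bottom, identifying each branching
#' node and its elements: a pre-order (parent before daughters, left before
#' right) enumeration of branch labels and terminal categories. Unlabeled
#' branches contribute the category-less marker `"_"`.
#'
#' @param t A `syntactic_object`.
#' @param config An [encoding_config()]; defaults to the calibrated
#'   node-terminal configuration.
#' @return A `symbol_sequence`.
#' @examples
#' encode_node_terminal(parse_bracketed("[a [l] [a [b] [g [d] [e]]]]"))
#' @export
encode_node_terminal <- function(t, config = tcc_default_config("node_terminal")) {
  rec <- function(x) {
    if (is_leaf(x)) return(leaf_symbol(x, config))
    lab <- if (is.na(x$label)) "_" else x$label
    c(lab, rec(x$left), rec(x$right))
  }
  syms <- rec(t); syms <- syms[!is.na(syms)]
  syms <- apply_policy(syms, config$symbol_policy)
  symbol_sequence(syms, provenance = "node_terminal")
}

#' Search-path serialization
#'
#' Encodes the node steps of a probe-goal search as symbols. Under the
#' calibrated configuration the sequence starts at the probe's maximal
#' projection and each search step contributes the pair of nodes it
#' connects, so interior nodes of the path appear twice
#' (`step_symbols = "transitions"`); `step_symbols = "nodes"` gives the
#' plain one-symbol-per-node path.
#'
#' @param result A `search_result` from [minimal_search()] or
#'   [search_to()]; must have found a goal.
#' @param config An [encoding_config()].
#' @return A `symbol_sequence`.
#' @export
encode_search_path <- function(result, config = tcc_default_config("search_path")) {
  stopifnot(inherits(result, "search_result"))
  if (is.null(result$goal) || length(result$path_labels) == 0L)
    stop("search result has no goal: empty path cannot be encoded", call. = FALSE)
  path <- result$path_labels
  if (config$include_origin) path <- c(result$origin_label, path)
  if (config$step_symbols == "transitions" && length(path) > 1L) {
    inner <- path[-c(1L, length(path))]
    path <- c(path[1L], rep(inner, each = 2L), path[length(path)])
  }
  symbol_sequence(apply_policy(path, config$symbol_policy),
                  provenance = "search_path")
}

#' Movement-path serialization
#'
#' One symbol per occurrence site of a movement chain, from the initially
#' merged base through intermediate landing sites to the terminal landing
#' site. Each site is represented by the label of the node immediately
#' dominating it (so a base position inside `V'` and a specifier of `VP`
#' receive different symbols under `per_distinct_label`).
#'
#' @param path List of site addresses, base first (see [movement_path()]).
#' @param t The `syntactic_object` containing the chain.
#' @param config An [encoding_config()].
#' @return A `symbol_sequence`.
#' @export
encode_movement_path <- function(path, t,
                                 config = tcc_default_config("movement_path")) {
  if (length(path) < 2L) stop("movement path needs at least 2 sites", call. = FALSE)
  syms <- vapply(path, function(a) {
    if (length(a) == 0L) return(node_symbol(t))
    parent <- subtree_at(t, a[-length(a)])
    s <- node_symbol(parent)
    if (is.na(s)) "_" else s
  }, "")
  symbol_sequence(apply_policy(syms, config$symbol_policy),
                  provenance = "movement_path")
}

#' Phrase-label serialization
#'
#' Enumerates the successive phrase labels of a structure left-to-right:
#' the category of each terminal-level phrase unit in surface order,
#' schematic workspace-stage labels (unlabeled or Greek-lettered branch
#' nodes) contributing nothing. Under the calibrated configuration lower
#' copies are visible and carry their antecedent's category symbol; with
#' `copy_policy = "invisible"` they are skipped, as when only pronounced
#' material is enumerated.
#'
#' @param t A `syntactic_object` with labels assigned (see [label_of()]).
#' @param config An [encoding_config()].
#' @return A `symbol_sequence`.
#' @export
encode_label_sequence <- function(t, config = tcc_default_config("label_sequence")) {
  rec <- function(x) {
    if (is_leaf(x)) return(leaf_symbol(x, config))
    c(rec(x$left), rec(x$right))
  }
  syms <- rec(t); syms <- syms[!is.na(syms)]
  symbol_sequence(apply_policy(syms, config$symbol_policy),
                  provenance = "label_sequence")
}

#' Binary recoding of a symbol sequence
#'
#' Recode symbols as binary strings (alphabet indices in order of first
#' appearance), either fixed-width or as minimal-width binary numerals.
#' Included because the reference Lempel-Ziv 76 formulation is defined over
#' binary strings.
#'
#' @param x A `symbol_sequence`.
#' @param method `"fixed"`, `"fixed1"`, `"minwidth"` or `"minwidth1"`
#'   (see [encoding_config()]); `"none"` returns `x` unchanged.
#' @return A `symbol_sequence` over `c("0", "1")`.
#' @export
binarize_sequence <- function(x, method = c("minwidth", "minwidth1",
                                            "fixed", "fixed1", "none")) {
  method <- match.arg(method)
  if (method == "none") return(x)
  stopifnot(inherits(x, "symbol_sequence"))
  idx <- match(x$symbols, x$alphabet) - 1L
  if (method %in% c("fixed1", "minwidth1")) idx <- idx + 1L
  to_bits <- function(v) {
    if (v == 0L) return("0")
    bits <- character(0)
    while (v > 0L) { bits <- c(as.character(v %% 2L), bits); v <- v %/% 2L }
    paste(bits, collapse = "")
  }
  codes <- vapply(idx, to_bits, "")
  if (startsWith(method, "fixed")) {
    w <- max(nchar(codes))
    codes <- paste0(strrep("0", w - nchar(codes)), codes)
  }
  bits <- unlist(strsplit(codes, ""), use.names = FALSE)
  symbol_sequence(bits, provenance = paste0(x$provenance %||% "", "|bin:", method))
}

#' Serialize sequences to TSV
#'
#' @param seqs List of `symbol_sequence`s (optionally named).
#' @param path Optional file path; if `NULL` the data frame is returned
#'   invisibly without writing.
#' @return A data frame with columns `id`, `provenance`, `n`,
#'   `alphabet_size`, `symbols`.
#' @export
sequences_to_tsv <- function(seqs, path = NULL) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  df <- data.frame(
    id = ids,
    provenance = vapply(seqs, function(s) s$provenance %||% "", ""),
    n = vapply(seqs, function(s) length(s$symbols), 0L),
    alphabet_size = vapply(seqs, function(s) length(s$alphabet), 0L),
    symbols = vapply(seqs, format, ""),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
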