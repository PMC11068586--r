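# The Turing-Chomsky Compression comparator, the Bulgarian wh-order
# predictor, the merge-closure enumerator, and the fixture runner.

#' Candidate for comparison
#'
#' @param id Candidate identifier.
#' @param sequence A `symbol_sequence` (already encoded), or `NULL` if
#'   `source`/`encode` are supplied.
#' @param mode Encoder mode the sequence came from (all candidates in one
#'   comparison must share it).
#' @param annotation Optional expected-grammaticality annotation
#'   (`"grammatical"` / `"ungrammatical"`), carried for fixture testing
#'   only and never consulted by the comparator.
#' @param binarize Binary recoding to apply at scoring time (usually the
#'   encoding configuration's `binarize`).
#' @return A `tcc_candidate`.
#' @export
tcc_candidate <- function(id, sequence, mode, annotation = NULL,
                          binarize = "none") {
  stopifnot(inherits(sequence, "symbol_sequence"))
  structure(list(id = id, sequence = sequence, mode = mode,
                 annotation = annotation, binarize = binarize),
            class = "tcc_candidate")
}

#' Compare candidates by normalized complexity
#'
#' The Turing-Chomsky Compression comparator: an operation on an accessible
#' object of a workspace is preferred when the structures resulting from it
#' compress to lower estimated Kolmogorov complexity than the alternative.
#' Candidates are ranked by ascending normalized complexity and the
#' licensed set is every candidate attaining the minimum (exact ties are
#' jointly licensed). All candidates must use the same encoder mode; the
#' comparator never consults grammaticality annotations.
#'
#' @param candidates List of [tcc_candidate()]s (at least two).
#' @param scheme A `complexity_scheme` or id; defaults to the calibrated
#'   scheme.
#' @return A `tcc_report`: `table` (per-candidate complexity results),
#'   `ranking` (ids, ascending), `licensed` (ids attaining the minimum),
#'   `margins` (pairwise differences of normalized complexity).
#' @export
tcc_compare <- function(candidates, scheme = complexity_scheme("ks_log2")) {
  stopifnot(length(candidates) >= 2L)
  modes <- unique(vapply(candidates, function(x) x$mode, ""))
  if (length(modes) != 1L)
    stop("mixed encoder modes in one comparison: ", paste(modes, collapse = ", "),
         call. = FALSE)
  res <- lapply(candidates, function(x)
    normalized_complexity(x$sequence, scheme, binarize = x$binarize,
                          warn_short = FALSE))
  ids <- vapply(candidates, function(x) x$id, "")
  vals <- vapply(res, function(r) r$normalized, 0)
  tab <- data.frame(id = ids,
                    phrase_count = vapply(res, function(r) r$phrase_count, 0L),
                    length = vapply(res, function(r) r$length, 0L),
                    alphabet_size = vapply(res, function(r) r$alphabet_size, 0L),
                    normalized = vals,
                    annotation = vapply(candidates, function(x)
                      x$annotation %||% NA_character_, ""),
                    stringsAsFactors = FALSE)
  ord <- order(vals, ids)                      # id as deterministic tie order
  licensed <- ids[abs(vals - min(vals)) < 1e-12]
  margins <- outer(vals, vals, "-")
  dimnames(margins) <- list(ids, ids)
  structure(list(table = tab[ord, , drop = FALSE],
                 ranking = ids[ord],
                 licensed = sort(licensed),
                 margins = margins,
                 scheme = if (is.character(scheme)) scheme else scheme$id,
                 mode = modes),
            class = "tcc_report")
}

#' @export
print.tcc_report <- function(x, ...) {
  cat(sprintf("<tcc_report mode=%s scheme=%s>\n", x$mode, x$scheme))
  print(x$table, row.names = FALSE, digits = 4)
  cat("licensed:", paste(x$licensed, collapse = ", "), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Bulgarian multiple wh-fronting
## ---------------------------------------------------------------------------

#' Predict licensed wh-fronting orders
#'
#' For a clause with several wh-phrases that must all front (as in
#' Bulgarian multiple wh-fronting), predicts which fronting orders are
#' licensed: minimal search from interrogative C selects the least-embedded
#' wh-phrase as the first mover (a lower wh-phrase moving first would cross
#' a featurally equal intervener); the remaining wh-phrases then front for
#' their own focus requirement, and every relative order among them is
#' licensed exactly when their movement encodings have equal normalized
#' complexity. Candidates that leave a wh-phrase in situ are blocked by its
#' unchecked focus feature.
#'
#' @param t A clause `syntactic_object` whose wh-phrases carry `+Q +Foc`
#'   (e.g. fixtures `ex10`-`ex12`).
#' @param scheme Complexity scheme for the equal-path comparison.
#' @return A data frame with one row per candidate order (`order`, a
#'   `"x<y<z"` string; `fronted`, how many front; `licensed`; `reason`).
#' @export
predict_wh_order <- function(t, scheme = complexity_scheme("ks_log2")) {
  wh <- find_leaves(t, function(x) "Q" %in% x$features && "Foc" %in% x$features &&
                      !x$lower)
  if (!length(wh)) stop("no wh-element in the structure", call. = FALSE)
  forms <- vapply(wh, function(a) subtree_at(t, a)$form, "")
  depths <- vapply(wh, length, 0L)
  k <- length(wh)
  first_mover <- forms[which.min(depths)]
  unique_min <- sum(depths == min(depths)) == 1L

  # movement-path complexity of each wh-phrase: base site to the C domain
  site_complexity <- function(a) {
    parent_lab <- {
      p <- subtree_at(t, a[-length(a)])
      s <- node_symbol(p); if (is.na(s)) "_" else s
    }
    seq <- symbol_sequence(c(parent_lab, node_symbol(t)))
    normalized_complexity(seq, scheme, warn_short = FALSE)$normalized
  }
  cx <- vapply(wh, site_complexity, 0)
  names(cx) <- forms

  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  candidates <- perms(forms)                          # full multiple fronting
  partial <- if (k >= 2L) lapply(forms, function(f) f) else list()

  judge_full <- function(ord) {
    if (!identical(ord[1L], first_mover) || !unique_min)
      return(list(FALSE, sprintf(
        "minimal search selects `%s` first; moving `%s` crosses an equal intervener",
        first_mover, ord[1L])))
    rest <- ord[-1L]
    if (length(rest) >= 2L && diff(range(cx[rest])) > 1e-12) {
      want <- rest[order(cx[rest], rest)]
      if (!identical(rest, want))
        return(list(FALSE, "remaining movers have unequal path complexity"))
    }
    list(TRUE, if (length(rest) >= 2L)
      "first mover least embedded; remaining paths of equal complexity, any order"
      else "first mover least embedded")
  }
  rows <- lapply(candidates, function(ord) {
    j <- judge_full(ord)
    data.frame(order = paste(ord, collapse = "<"), fronted = length(ord),
               licensed = j[[1L]], reason = j[[2L]], stringsAsFactors = FALSE)
  })
  rows_p <- lapply(partial, function(f) {
    insitu <- setdiff(forms, f)
    data.frame(order = sprintf("%s (%s in situ)", f, paste(insitu, collapse = ",")),
               fronted = 1L, licensed = FALSE,
               reason = sprintf("wh-phrase(s) %s left in situ with unchecked focus feature",
                                paste(insitu, collapse = ", ")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, rows_p))
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## MERGE-closure enumeration
## ---------------------------------------------------------------------------

# parse a canonical set expression back into nested pair lists (for subterm
# enumeration during closure search)
parse_canonical <- function(s) {
  if (!startsWith(s, "{")) return(s)
  inner <- substr(s, 2L, nchar(s) - 1L)
  depth_ <- 0L
  chars <- strsplit(inner, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "{") depth_ <- depth_ + 1L
    else if (ch == "}") depth_ <- depth_ - 1L
    else if (ch == "," && depth_ == 0L)
      return(list(substr(inner, 1L, i - 1L), substr(inner, i + 1L, nchar(inner))))
  }
  stop("malformed canonical form: ", s, call. = FALSE)
}

subterm_strings <- function(s, cache) {
  if (exists(s, envir = cache)) return(get(s, envir = cache))
  out <- s
  if (startsWith(s, "{")) {
    kids <- parse_canonical(s)
    out <- unique(c(s, subterm_strings(kids[[1L]], cache),
                    subterm_strings(kids[[2L]], cache)))
  }
  assign(s, out, envir = cache)
  out
}

set_of <- function(a, b) {
  kids <- sort(c(a, b))
  paste0("{", kids[1L], ",", kids[2L], "}")
}

#' Enumerate the MERGE closure of a lexicon
#'
#' Exhaustively enumerates the distinct workspaces reachable within a given
#' number of MERGE steps, with canonical-form deduplication (`{X,Y}` is
#' `{Y,X}`; a copy is the same object as its antecedent). Operations are
#' external merge of a lexical item with a root, external merge of two
#' roots, and internal merge of any subterm to its root's edge. With
#' `allow_reuse = FALSE` each lexical item enters the derivation once (a
#' lexical-array regime); with `allow_reuse = TRUE` items may re-enter
#' without bound, which is the regime under which the closure from two
#' elements grows to millions of sets within eight steps. With
#' `restrict = TRUE` only Resource-Restriction-compliant steps are taken
#' (all engine-generated operations comply, so the restricted and
#' unrestricted closures coincide for this operation inventory; the flag
#' exists so hypothetical operation sets can be screened).
#'
#' @param lexicon Named list of [lex_item()]s, or a character vector of
#'   item names.
#' @param max_steps Number of MERGE steps to enumerate.
#' @param restrict Take only Resource-Restriction-compliant steps.
#' @param allow_reuse Allow repeated selection of the same lexical item.
#' @param max_workspaces Resource cap; if the frontier would exceed it the
#'   result is truncated and flagged.
#' @return Data frame with `step` and `distinct_workspaces` (cumulative
#'   count of distinct workspace states reached at each step), with
#'   attributes `truncated` (logical) and `coincident` (number of states
#'   reached by more than one history, informing the Markov check).
#' @export
enumerate_merge_closure <- function(lexicon, max_steps, restrict = FALSE,
                                    allow_reuse = FALSE,
                                    max_workspaces = 200000L) {
  if (is.character(lexicon)) {
    nms <- lexicon
    lexicon <- lapply(nms, function(nm) lex_item("N", nm))
    names(lexicon) <- nms
  }
  lex_strings <- vapply(lexicon, canonical_so, "")
  names(lex_strings) <- names(lexicon)
  cache <- new.env(parent = emptyenv())

  # state: sorted character vector of canonical root strings; the
  # enumeration starts from the workspace holding every lexical item
  state_key <- function(roots) paste(roots, collapse = " | ")
  start <- sort(unname(lex_strings))
  seen <- new.env(parent = emptyenv(), size = 4096L)
  assign(state_key(start), 1L, envir = seen)
  frontier <- list(start)
  counts <- integer(max_steps)
  truncated <- FALSE
  coincident <- 0L
  n_seen <- 1L

  # accessible elements for the Resource-Restriction screen: distinct
  # subterm sets across the roots, plus the roots as syntactic objects
  rr_of <- function(roots) {
    if (!length(roots)) return(0L)
    length(unique(unlist(lapply(roots, subterm_strings, cache = cache)))) +
      length(roots)
  }

  successors <- function(roots) {
    out <- list()
    nr <- length(roots)
    add <- function(new_roots) out[[length(out) + 1L]] <<- sort(new_roots)
    if (allow_reuse)
      for (lx in lex_strings) for (j in seq_len(nr))
        add(c(roots[-j], set_of(lx, roots[j])))
    if (nr >= 2L)
      for (i in seq_len(nr - 1L)) for (j in seq((i + 1L), nr))
        add(c(roots[-c(i, j)], set_of(roots[i], roots[j])))
    for (j in seq_len(nr)) {
      if (!startsWith(roots[j], "{")) next
      for (sub in subterm_strings(roots[j], cache)) {
        if (identical(sub, roots[j])) next
        add(c(roots[-j], set_of(sub, roots[j])))
      }
    }
    out
  }

  for (step in seq_len(max_steps)) {
    nxt <- list()
    for (st in frontier) {
      before_rr <- rr_of(st)
      for (s2 in successors(st)) {
        if (restrict && rr_of(s2) - before_rr > 1L) next
        key <- state_key(s2)
        if (exists(key, envir = seen)) {
          coincident <- coincident + 1L
          next
        }
        assign(key, 1L, envir = seen)
        n_seen <- n_seen + 1L
        nxt[[length(nxt) + 1L]] <- s2
        if (n_seen > max_workspaces) {
          truncated <- TRUE
          break
        }
      }
      if (truncated) break
    }
    frontier <- nxt
    counts[step] <- length(nxt)
    if (truncated || !length(frontier)) break
  }
  out <- data.frame(step = seq_len(max_steps),
                    distinct_workspaces = cumsum(counts))
  attr(out, "truncated") <- truncated
  attr(out, "coincident") <- coincident
  out
}

## ---------------------------------------------------------------------------
## Fixture runner
## ---------------------------------------------------------------------------

#' Run a worked-example fixture
#'
#' Reproduces one of the worked-example analyses end to end and checks the
#' outcome against the grammaticality annotation. Available fixtures:
#' `"ex2_compression"` (node/terminal complexity of the adjunction pair),
#' `"ex2_tamper"` (the same pair through the No-Tampering checker),
#' `"ex3_rm"` (Relativised Minimality, complexity not consulted),
#' `"ex6_search"` (search-path complexity), `"ex9_movement"`
#' (movement-path complexity), `"ex13_labeling"` (phrase-label complexity),
#' `"ex10_bulgarian"`, `"ex11_bulgarian"`, `"ex12_bulgarian"` (wh-fronting
#' orders).
#'
#' @param name Fixture analysis name.
#' @param scheme Complexity scheme.
#' @return A list with a `pass` flag, the expected outcome, and the
#'   underlying report (a `tcc_report`, checker output, or wh-order table).
#' @export
run_fixture <- function(name, scheme = complexity_scheme("ks_log2")) {
  switch(name,
    ex2_compression = {
      rep <- tcc_compare(list(
        fixture_candidate("ex2b", "grammatical"),
        fixture_candidate("ex2c", "ungrammatical")), scheme)
      list(pass = identical(rep$licensed, "ex2b"), expected = "ex2b", report = rep)
    },
    ex2_tamper = {
      ws0 <- workspace(list(l = lex_item("l")),
                       roots = list(tcc_fixture("ex2a")))
      ws1 <- merge_external(ws0, "l", 1L, label = "a")
      ok_b <- check_no_tampering(last_step(ws1))
      tampered <- list(before = ws0,
                       after = workspace(roots = list(tcc_fixture("ex2c"))))
      ok_c <- check_no_tampering(tampered)
      list(pass = ok_b$pass && !ok_c$pass, expected = "ex2b extends, ex2c tampers",
           report = list(ex2b = ok_b, ex2c = ok_c))
    },
    ex3_rm = {
      t3a <- tcc_fixture("ex3a"); t3b <- tcc_fixture("ex3b")
      res_a <- rm_check(t3a, probe(address_of_leaf(
        t3a, function(x) identical(x$form, "do")), "Q"), deepest_copy(t3a, 1L))
      res_b <- rm_check(t3b, probe(address_of_leaf(
        t3b, function(x) identical(x$form, "do")), "Q"), deepest_copy(t3b, 1L))
      list(pass = !res_a$licensed && res_b$licensed,
           expected = "ex3a blocked, ex3b licensed",
           report = list(ex3a = res_a, ex3b = res_b))
    },
    ex6_search = {
      rep <- tcc_compare(list(
        fixture_candidate("ex6b_CV", "grammatical"),
        fixture_candidate("ex6b_CTP", "ungrammatical")), scheme)
      list(pass = identical(rep$licensed, "ex6b_CV"), expected = "ex6b_CV",
           report = rep)
    },
    ex9_movement = {
      rep <- tcc_compare(list(
        fixture_candidate("ex9a", "ungrammatical"),
        fixture_candidate("ex9b", "grammatical")), scheme)
      list(pass = identical(rep$licensed, "ex9b"), expected = "ex9b", report = rep)
    },
    ex13_labeling = {
      rep <- tcc_compare(list(
        fixture_candidate("ex13a", "ungrammatical"),
        fixture_candidate("ex13b", "grammatical")), scheme)
      list(pass = identical(rep$licensed, "ex13b"), expected = "ex13b", report = rep)
    },
    ex10_bulgarian = bulgarian_fixture("ex10", "koj<kogo", scheme),
    ex11_bulgarian = bulgarian_fixture("ex11", "kogo<kakvo", scheme),
    ex12_bulgarian = bulgarian_fixture("ex12",
                                       c("koj<kogo<kakvo", "koj<kakvo<kogo"),
                                       scheme),
    stop("unknown fixture analysis: ", name, call. = FALSE))
}

bulgarian_fixture <- function(fix, expected, scheme) {
  tab <- predict_wh_order(tcc_fixture(fix), scheme)
  got <- sort(tab$order[tab$licensed])
  list(pass = identical(got, sort(expected)), expected = expected, report = tab)
}

# Build the candidate (id, encoded sequence, mode) for one member of a
# printed contrast, under the calibrated per-mode configuration.
fixture_candidate <- function(id, annotation = NULL) {
  pairs <- tcc_printed_targets()
  for (pair in pairs) {
    hit <- match(id, pair$labels)
    if (!is.na(hit)) {
      cfg <- tcc_default_config(pair$mode)
      seqs <- pair$encode(cfg)
      return(tcc_candidate(id, seqs[[hit]], pair$mode, annotation,
                           binarize = cfg$binarize))
    }
  }
  stop("unknown fixture candidate: ", id, call. = FALSE)
}
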