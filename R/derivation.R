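# MERGE engine over workspaces, and the economy-condition checkers.

#' Lexical items and workspaces
#'
#' A workspace is the multiset of root syntactic objects available to a
#' derivation, together with the lexicon it draws from. MERGE maps workspace
#' *n* to workspace *n + 1*; the lexicon is a standing resource and is not
#' consumed by inspection, only by use.
#'
#' @param lexicon Named list of `syntactic_object` leaves (see [lex_item()]).
#' @param roots List of root `syntactic_object`s (usually empty at the
#'   start).
#' @return A `workspace` object.
#' @export
workspace <- function(lexicon = list(), roots = list()) {
  stopifnot(is.list(lexicon), is.list(roots))
  if (length(lexicon) && is.null(names(lexicon)))
    names(lexicon) <- vapply(lexicon, function(x) x$form, "")
  structure(list(roots = roots, lexicon = lexicon, history = list()),
            class = "workspace")
}

#' @rdname workspace
#' @param category,form,features Passed to [so_leaf()].
#' @export
lex_item <- function(category, form = NULL, features = character()) {
  so_leaf(category, form = form, features = features)
}

#' @export
print.workspace <- function(x, ...) {
  cat(sprintf("<workspace: %d root(s), %d lexical item(s), size %d>\n",
              length(x$roots), length(x$lexicon), workspace_size(x)))
  for (i in seq_along(x$roots))
    cat(sprintf("  [%d] %s\n", i, write_bracketed(x$roots[[i]], compact_copies = TRUE)))
  invisible(x)
}

strip_history <- function(ws) { ws$history <- list(); ws }

new_step <- function(kind, operands, before, after) {
  structure(list(kind = kind, operands = operands,
                 before = strip_history(before), after = strip_history(after)),
            class = "derivation_step")
}

#' Most recent derivation step
#'
#' @param ws A `workspace` produced by [merge_external()] or
#'   [merge_internal()].
#' @return A `derivation_step` (kind, operands, before/after workspaces), or
#'   `NULL` for a fresh workspace.
#' @export
last_step <- function(ws) {
  if (length(ws$history)) ws$history[[length(ws$history)]] else NULL
}

resolve_operand <- function(ws, x) {
  # x: a lexicon name, a root index, or a syntactic_object
  if (inherits(x, "syntactic_object")) return(list(obj = x, root = NA_integer_))
  if (is.character(x)) {
    if (!x %in% names(ws$lexicon))
      stop("unknown lexical item: ", x, call. = FALSE)
    return(list(obj = ws$lexicon[[x]], root = NA_integer_))
  }
  i <- as.integer(x)
  if (is.na(i) || i < 1L || i > length(ws$roots))
    stop("not a root of the workspace: ", x, call. = FALSE)
  list(obj = ws$roots[[i]], root = i)
}

#' External MERGE
#'
#' Forms the set `{X, Y}` from a new element `x` (a lexical item or another
#' root) and an existing root `y`, embedding both unchanged. The new set
#' replaces `y` among the roots; if `x` was itself a root it is removed
#' (it has been consumed).
#'
#' @param ws A `workspace`.
#' @param x Lexicon name (character), root index, or a `syntactic_object`.
#' @param y Root index of the object merged with.
#' @param label Optional label for the new set; `NULL` leaves the set
#'   unlabeled (labeling may apply later, see [label_of()]).
#' @return The new `workspace`; the step is recorded in its history (see
#'   [last_step()]).
#' @export
merge_external <- function(ws, x, y, label = NULL) {
  stopifnot(inherits(ws, "workspace"))
  yi <- as.integer(y)
  if (is.na(yi) || yi < 1L || yi > length(ws$roots))
    stop("y is not a root of the workspace", call. = FALSE)
  xr <- resolve_operand(ws, x)
  if (!is.na(xr$root) && xr$root == yi)
    stop("cannot externally merge a root with itself", call. = FALSE)
  out <- ws
  new_root <- so_branch(xr$obj, ws$roots[[yi]], label = label)
  keep <- setdiff(seq_along(ws$roots), c(yi, xr$root))
  out$roots <- c(ws$roots[keep], list(new_root))
  step <- new_step("external_merge", list(x = x, y = y, label = label), ws, out)
  out$history <- c(ws$history, list(step))
  out
}

#' Internal MERGE (movement)
#'
#' Re-merges an existing subterm of a root at that root's edge, leaving a
#' full lower copy in situ. The copy and its antecedent share a fresh copy
#' index; the previously built structure is not altered (No Tampering), the
#' in-situ occurrence is only flagged as the lower, unpronounced member of
#' the chain.
#'
#' @param ws A `workspace`.
#' @param root Root index.
#' @param target Address of the subterm to re-merge (must be a proper
#'   subterm: internal merge of the root with itself is excluded).
#' @param label Optional label of the new set.
#' @return The new `workspace`.
#' @export
merge_internal <- function(ws, root, target, label = NULL) {
  stopifnot(inherits(ws, "workspace"))
  ri <- as.integer(root)
  if (is.na(ri) || ri < 1L || ri > length(ws$roots))
    stop("not a root of the workspace: ", root, call. = FALSE)
  base <- ws$roots[[ri]]
  if (length(target) == 0L)
    stop("internal merge of the root with itself is excluded", call. = FALSE)
  if (!is_valid_address(base, target))
    stop("invalid address for internal merge target", call. = FALSE)
  moved <- subtree_at(base, target)
  idx <- max(0L, existing_copy_indices(base)) + 1L
  upper <- mark_copy(moved, idx, lower = FALSE)
  lowered <- replace_at(base, target, mark_copy(moved, idx, lower = TRUE))
  out <- ws
  out$roots[[ri]] <- so_branch(upper, lowered, label = label)
  step <- new_step("internal_merge",
                   list(root = root, target = target, label = label), ws, out)
  out$history <- c(ws$history, list(step))
  out
}

existing_copy_indices <- function(t) {
  out <- if (!is.na(t$copy_index)) t$copy_index else integer(0)
  if (is_branch(t)) out <- c(out, existing_copy_indices(t$left),
                             existing_copy_indices(t$right))
  out
}

mark_copy <- function(t, idx, lower) {
  t$copy_index <- as.integer(idx)
  t$lower <- isTRUE(lower)
  t
}

replace_at <- function(t, address, value) {
  if (length(address) == 0L) return(value)
  step <- address[[1L]]
  t[[step]] <- replace_at(t[[step]], address[-1L], value)
  t
}

## ---------------------------------------------------------------------------
## Economy conditions
## ---------------------------------------------------------------------------

occurs_in <- function(sub, t) {
  if (so_equal(sub, t, ignore_copy_marks = TRUE)) return(TRUE)
  if (is_leaf(t)) return(FALSE)
  occurs_in(sub, t$left) || occurs_in(sub, t$right)
}

#' No Tampering Condition
#'
#' A set created by MERGE cannot be broken and no new features can be added:
#' every root of the step's *before* workspace must occur node-identically
#' (up to copy bookkeeping) somewhere in the *after* workspace. Structure
#' may only be extended at the root, never modified internally.
#'
#' @param step A `derivation_step` (see [last_step()]), or a list with
#'   `before` and `after` workspaces.
#' @return A list with `pass` (logical) and, on violation, `witness`, the
#'   address (within the disturbed before-root) of the smallest subtree whose
#'   daughters all survive but which itself does not.
#' @export
check_no_tampering <- function(step) {
  before <- step$before; after <- step$after
  stopifnot(inherits(before, "workspace"), inherits(after, "workspace"))
  in_after <- function(sub) any(vapply(after$roots, function(r) occurs_in(sub, r), TRUE))
  for (r in before$roots) {
    if (in_after(r)) next
    # find a minimal disturbed subtree as a witness
    witness <- character(0)
    node <- r
    repeat {
      if (is_leaf(node)) break
      lok <- in_after(node$left); rok <- in_after(node$right)
      if (lok && rok) break                 # daughters intact, this set broken
      if (!lok) { witness <- c(witness, "left"); node <- node$left }
      else { witness <- c(witness, "right"); node <- node$right }
    }
    return(list(pass = FALSE, witness = witness))
  }
  list(pass = TRUE, witness = NULL)
}

count_subterms <- function(t, count_root = TRUE) {
  # subterms of a root; a lower copy is the same object as its antecedent and
  # contributes nothing new
  n_nodes <- function(x) {
    if (x$lower) return(0L)
    if (is_leaf(x)) 1L else 1L + n_nodes(x$left) + n_nodes(x$right)
  }
  n <- n_nodes(t)
  if (!count_root && n > 0L) n - 1L else n
}

#' Workspace size and accessible terms
#'
#' The size of a workspace is the number of accessible terms plus the number
#' of syntactic objects (roots). Accessible terms are all subterms of all
#' roots, the root object itself included (set `count_root_as_term = FALSE`
#' for the alternative convention under which a root is counted only as a
#' syntactic object); lower copies are the same object as their antecedent
#' and are counted once.
#'
#' @param ws A `workspace`.
#' @param count_root_as_term Logical; see above.
#' @return Non-negative integer.
#' @export
workspace_size <- function(ws, count_root_as_term = TRUE) {
  accessible_terms(ws, count_root_as_term) + length(ws$roots)
}

#' @rdname workspace_size
#' @export
accessible_terms <- function(ws, count_root_as_term = TRUE) {
  if (!length(ws$roots)) return(0L)
  sum(vapply(ws$roots, count_subterms, 0L, count_root = count_root_as_term))
}

# Constructed-object count used by the Resource-Restriction check: sets built
# so far (branch nodes, lower copies excluded) plus the roots holding them.
# Lexical items are accessible from the lexicon throughout, so the first use
# of an item does not in itself enlarge the resource pool.
rr_count <- function(ws) {
  n_branch <- function(x) {
    if (x$lower || is_leaf(x)) return(0L)
    1L + n_branch(x$left) + n_branch(x$right)
  }
  if (!length(ws$roots)) return(0L)
  sum(vapply(ws$roots, n_branch, 0L)) + length(ws$roots)
}

#' Resource Restriction
#'
#' When MERGE maps workspace *n* to workspace *n + 1*, the number of
#' computationally accessible elements may increase by at most one. Both
#' forms of MERGE provided by the engine satisfy this by construction
#' (external merge builds exactly one new set; internal merge builds one new
#' set and a copy that is not a new object); steps that duplicate existing
#' material into the workspace violate it.
#'
#' @param step A `derivation_step`, or a list with `before`/`after`
#'   workspaces.
#' @return List with `pass` (logical) and `delta`, the measured increase.
#' @export
check_resource_restriction <- function(step) {
  before <- step$before; after <- step$after
  stopifnot(inherits(before, "workspace"), inherits(after, "workspace"))
  delta <- rr_count(after) - rr_count(before)
  list(pass = delta <= 1L, delta = delta)
}

## ---------------------------------------------------------------------------
## Canonical forms and the Markov property
## ---------------------------------------------------------------------------

# Canonical string of a syntactic object under set semantics: {X,Y} = {Y,X},
# copy bookkeeping ignored (a copy is the same object).
canonical_so <- function(t) {
  if (is_leaf(t)) {
    feats <- paste(sort(t$features), collapse = "+")
    paste0(t$category, ":", if (is.na(t$form)) "" else t$form,
           if (nzchar(feats)) paste0("[", feats, "]") else "")
  } else {
    kids <- sort(c(canonical_so(t$left), canonical_so(t$right)))
    paste0("{", kids[1L], ",", kids[2L], "}")
  }
}

#' Canonical form of a workspace
#'
#' Roots as an unordered multiset of canonical set expressions; used for
#' workspace identity in [markov_check()] and
#' [enumerate_merge_closure()].
#'
#' @param ws A `workspace`.
#' @return A single string.
#' @export
canonical_workspace <- function(ws) {
  paste(sort(vapply(ws$roots, canonical_so, "")), collapse = " | ")
}

# Enumerate the legal MERGE operations available from a workspace, as
# canonical descriptor strings (used by markov_check).
legal_operations <- function(ws) {
  ops <- character(0)
  nr <- length(ws$roots)
  for (nm in names(ws$lexicon))
    for (j in seq_len(nr))
      ops <- c(ops, paste0("EM lex:", nm, " + ", canonical_so(ws$roots[[j]])))
  if (nr >= 2L)
    for (i in seq_len(nr - 1L)) for (j in seq((i + 1L), nr)) {
      pair <- sort(c(canonical_so(ws$roots[[i]]), canonical_so(ws$roots[[j]])))
      ops <- c(ops, paste0("EM ", pair[1L], " + ", pair[2L]))
    }
  for (j in seq_len(nr)) {
    r <- ws$roots[[j]]
    if (!is_branch(r)) next
    for (a in all_addresses(r)) {
      if (length(a) == 0L) next
      sub <- subtree_at(r, a)
      if (sub$lower) next
      ops <- c(ops, paste0("IM ", canonical_so(sub), " -> ", canonical_so(r)))
    }
  }
  unique(ops)
}

#' Markov property of derivations
#'
#' Resource Restriction renders derivations strictly Markovian: the legal
#' continuations of a derivation depend only on the current workspace, not
#' on how it was reached. Given two derivation histories ending in equal
#' workspaces, the sets of legal successor MERGE operations must coincide.
#'
#' @param ws1,ws2 Workspaces carrying their histories (as produced by
#'   chained [merge_external()] / [merge_internal()] calls).
#' @return `TRUE` iff the successor-operation sets are identical.
#' @export
markov_check <- function(ws1, ws2) {
  stopifnot(inherits(ws1, "workspace"), inherits(ws2, "workspace"))
  if (!identical(canonical_workspace(ws1), canonical_workspace(ws2)))
    stop("histories do not end in equal workspaces", call. = FALSE)
  setequal(legal_operations(ws1), legal_operations(ws2))
}

## ---------------------------------------------------------------------------
## Derivation scripts
## ---------------------------------------------------------------------------

#' Replay a derivation script
#'
#' Deterministically replays a plain-text derivation script, one operation
#' per line: `EM <item|root-id> <root-id> [label]` or
#' `IM <root-id> <address> [label]`, where `<address>` is a string over
#' `l`/`r` (e.g. `lrl`). Lines starting with `#` and blank lines are
#' ignored. A root id is its 1-based position in the current root list.
#'
#' @param lines Character vector of script lines, or a path to a script
#'   file.
#' @param lexicon Named list of [lex_item()]s.
#' @return The final `workspace`; the full step log is in its history and
#'   can be serialized with [derivation_log()].
#' @export
replay_script <- function(lines, lexicon) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  ws <- workspace(lexicon)
  for (raw in lines) {
    line <- trimws(raw)
    if (!nzchar(line) || startsWith(line, "#")) next
    parts <- strsplit(line, "\\s+")[[1]]
    op <- toupper(parts[[1L]])
    if (op == "EM") {
      x <- parts[[2L]]
      if (grepl("^[0-9]+$", x)) x <- as.integer(x)
      y <- as.integer(parts[[3L]])
      # bootstrap: EM into an empty workspace seeds a single-item root
      if (length(ws$roots) == 0L && is.character(x) && y == 1L) {
        ws$roots <- list(ws$lexicon[[x]])
        next
      }
      ws <- merge_external(ws, x, y, label = if (length(parts) > 3L) parts[[4L]])
    } else if (op == "IM") {
      root <- as.integer(parts[[2L]])
      addr <- chartr("lr", "LR", parts[[3L]])
      address <- c("left", "right")[match(strsplit(addr, "")[[1]], c("L", "R"))]
      ws <- merge_internal(ws, root, address,
                           label = if (length(parts) > 3L) parts[[4L]])
    } else stop("unknown script operation: ", op, call. = FALSE)
  }
  ws
}

#' JSON log of a derivation
#'
#' @param ws A `workspace` with history.
#' @return JSON string describing each step (kind, operands, resulting
#'   roots, economy checks).
#' @export
derivation_log <- function(ws) {
  steps <- lapply(ws$history, function(s) {
    list(kind = s$kind,
         operands = lapply(s$operands, function(o)
           if (is.null(o)) NULL else paste(as.character(o), collapse = "/")),
         after = vapply(s$after$roots, write_bracketed, "",
                        compact_copies = TRUE),
         no_tampering = check_no_tampering(s)$pass,
         resource_restriction = check_resource_restriction(s)$pass)
  })
  jsonlite::toJSON(steps, auto_unbox = TRUE, pretty = TRUE, null = "null")
}
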