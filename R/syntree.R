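# Bare-phrase-structure trees: constructors, labeled-bracket I/O, geometry.

#' Default category inventory
#'
#' Base categorial symbols recognised by [parse_bracketed()]. Phrasal (`"DP"`)
#' and bar-level (`"T'"`) variants of a base category are accepted
#' automatically. Single lower-case letters stand in for the Greek letters
#' used in schematic workspace structures (`a` = alpha, `b` = beta,
#' `g` = gamma, `d` = delta, `e` = epsilon, `l` = lambda).
#'
#' @return Character vector of base category symbols.
#' @export
default_categories <- function() {
  c("C", "T", "v", "V", "N", "D", "P", "A", "Adv", "Q", "Det", "Asp",
    "Cl", "Neg", "Foc",
    "a", "b", "g", "d", "e", "l")
}

base_category <- function(cat) {
  # strip one bar level, then one phrasal "P" ("PP" -> "P", "P" stays "P")
  x <- sub("'$", "", cat)
  ifelse(nchar(x) > 1 & grepl("P$", x), sub("P$", "", x), x)
}

#' Construct a lexical leaf
#'
#' @param category Categorial symbol (e.g. `"D"`, `"V"`, `"TP"`).
#' @param form Surface form, or `NULL` for silent heads (null C, unpronounced
#'   T, schematic items).
#' @param features Character vector of formal feature names carried by the
#'   item; `"Q"` renders as `[+Q]`. Duplicates are dropped.
#' @param copy_index Integer shared by all occurrences of a moved element, or
#'   `NULL`.
#' @param lower Logical; `TRUE` marks this occurrence as a silent lower copy.
#' @return A `syntactic_object` of kind `"leaf"`.
#' @export
so_leaf <- function(category, form = NULL, features = character(),
                    copy_index = NULL, lower = FALSE) {
  stopifnot(is.character(category), length(category) == 1L, nzchar(category))
  structure(list(kind = "leaf", category = category,
                 form = if (is.null(form)) NA_character_ else form,
                 features = unique(as.character(features)),
                 copy_index = if (is.null(copy_index)) NA_integer_
                              else as.integer(copy_index),
                 lower = isTRUE(lower)),
            class = "syntactic_object")
}

#' Construct a binary branch
#'
#' Binary branching is enforced by the constructor signature: a branch has
#' exactly a left and a right daughter.
#'
#' @param left,right Daughter `syntactic_object`s.
#' @param label Categorial label of the set, or `NULL` for an unlabeled
#'   (adjunction-style) node.
#' @param copy_index,lower As in [so_leaf()], for full lower copies of
#'   phrases.
#' @return A `syntactic_object` of kind `"branch"`.
#' @export
so_branch <- function(left, right, label = NULL, copy_index = NULL,
                      lower = FALSE) {
  stopifnot(inherits(left, "syntactic_object"),
            inherits(right, "syntactic_object"))
  structure(list(kind = "branch",
                 label = if (is.null(label)) NA_character_ else label,
                 left = left, right = right,
                 copy_index = if (is.null(copy_index)) NA_integer_
                              else as.integer(copy_index),
                 lower = isTRUE(lower)),
            class = "syntactic_object")
}

#' Node kind predicates
#'
#' @param t A `syntactic_object`.
#' @return Logical scalar.
#' @export
is_leaf <- function(t) identical(t$kind, "leaf")

#' @rdname is_leaf
#' @export
is_branch <- function(t) identical(t$kind, "branch")

#' @export
print.syntactic_object <- function(x, ...) {
  cat(write_bracketed(x), "\n")
  invisible(x)
}

# node label used for path/sequence purposes: branch label, or leaf category
node_symbol <- function(t) {
  if (is_branch(t)) t$label else t$category
}

## ---------------------------------------------------------------------------
## Labeled-bracket parser
##
## Dialect (one canonical rendering of the mixed styles found in print):
##   branch            [Label child child]     label may be omitted: [ x y ]
##   leaf              [Cat] | [Cat form] | [Cat form +F +G] | [Cat +F]
##   trace leaf        [<Cat>#i]
##   antecedent        [...]#i      (any node followed by a copy index)
##   lower full copy   [<Label> child child]#i
## ---------------------------------------------------------------------------

tokenize_brackets <- function(text) {
  text <- gsub("\\[", " [ ", text)
  text <- gsub("\\]", " ] ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

parse_error <- function(msg, toks, pos) {
  span <- paste(toks[max(1L, pos - 3L):min(length(toks), pos + 3L)],
                collapse = " ")
  stop(sprintf("parse error near token %d (`%s`): %s", pos, span, msg),
       call. = FALSE)
}

#' Parse labeled bracket notation
#'
#' Reads one syntactic object from a labeled-bracket string (see
#' *Details*). Round-trips with [write_bracketed()]: parsing the written
#' form of a tree gives back the identical tree.
#'
#' @details The dialect is `[Label child child]` for branches (the label may
#'   be omitted for unlabeled adjunction nodes), `[Cat form +F ...]` for
#'   leaves (form and features optional; silent heads are `[T]`, `[C]`), a
#'   trailing `#i` to mark the antecedent of a movement chain, and
#'   `[<Cat>#i]` for the silent lower copy left behind by internal MERGE.
#'   Features and forms of lower copies are inherited from their antecedent,
#'   so every occurrence of a chain carries identical category and features.
#'
#' @param text Labeled-bracket string (UTF-8, whitespace-insensitive).
#' @param categories Base category inventory used to validate labels, or
#'   `NULL` to skip validation. Defaults to [default_categories()].
#' @return A `syntactic_object`.
#' @seealso [write_bracketed()]
#' @examples
#' parse_bracketed("[N dog]")
#' parse_bracketed("[a [l] [a [b] [g [d] [e]]]]")
#' @export
parse_bracketed <- function(text, categories = default_categories()) {
  toks <- tokenize_brackets(text)
  if (length(toks) == 0L) stop("empty input", call. = FALSE)
  env <- new.env(parent = emptyenv())
  env$pos <- 1L

  peek <- function() if (env$pos <= length(toks)) toks[[env$pos]] else NA_character_
  advance <- function() { tok <- peek(); env$pos <- env$pos + 1L; tok }

  check_cat <- function(cat, what = "category") {
    if (!is.null(categories) && !(base_category(cat) %in% categories))
      parse_error(sprintf("unknown %s `%s`", what, cat), toks, env$pos - 1L)
    cat
  }

  read_copy_suffix <- function() {
    tok <- peek()
    if (!is.na(tok) && grepl("^#[0-9]+$", tok)) {
      env$pos <- env$pos + 1L
      as.integer(sub("^#", "", tok))
    } else NULL
  }

  parse_node <- function() {
    tok <- advance()
    if (!identical(tok, "[")) parse_error("expected `[`", toks, env$pos - 1L)
    head_tok <- peek()
    if (is.na(head_tok)) parse_error("unbalanced brackets", toks, env$pos)

    # trace leaf [<Cat>#i]
    if (grepl("^<[^>]+>#[0-9]+$", head_tok)) {
      advance()
      if (!identical(advance(), "]"))
        parse_error("expected `]` after trace", toks, env$pos - 1L)
      cat <- check_cat(sub("^<([^>]+)>#[0-9]+$", "\\1", head_tok))
      idx <- as.integer(sub("^<[^>]+>#([0-9]+)$", "\\1", head_tok))
      return(so_leaf(cat, copy_index = idx, lower = TRUE))
    }

    lower <- FALSE
    label <- NULL
    if (grepl("^<[^>]+>$", head_tok)) {          # lower full copy label
      advance()
      lower <- TRUE
      label <- check_cat(sub("^<([^>]+)>$", "\\1", head_tok), "label")
    } else if (!identical(head_tok, "[")) {
      advance()
      label <- head_tok                          # validated once kind is known
    }

    nxt <- peek()
    if (identical(nxt, "[")) {                   # branch: parse children
      if (!is.null(label) && !lower) check_cat(label, "label")
      children <- list()
      while (identical(peek(), "[")) children[[length(children) + 1L]] <- parse_node()
      if (!identical(advance(), "]"))
        parse_error("expected `]`", toks, env$pos - 1L)
      if (length(children) != 2L)
        parse_error(sprintf("branch has %d children, need exactly 2",
                            length(children)), toks, env$pos - 1L)
      idx <- read_copy_suffix()
      if (lower && is.null(idx))
        parse_error("lower copy needs a `#i` copy index", toks, env$pos - 1L)
      return(so_branch(children[[1L]], children[[2L]], label = label,
                       copy_index = idx, lower = lower))
    }

    # leaf: [Cat], [Cat form], [Cat form +F ...], [Cat +F ...]
    if (is.null(label)) parse_error("leaf without category", toks, env$pos - 1L)
    check_cat(label)
    form <- NULL
    features <- character()
    repeat {
      tok <- peek()
      if (is.na(tok)) parse_error("unbalanced brackets", toks, env$pos)
      if (identical(tok, "]")) { advance(); break }
      advance()
      if (grepl("^\\+", tok)) features <- c(features, sub("^\\+", "", tok))
      else if (is.null(form) && length(features) == 0L) form <- tok
      else parse_error(sprintf("unexpected token `%s` in leaf", tok),
                       toks, env$pos - 1L)
    }
    idx <- read_copy_suffix()
    so_leaf(label, form = form, features = features, copy_index = idx)
  }

  out <- parse_node()
  if (env$pos <= length(toks))
    parse_error("trailing input after structure", toks, env$pos)
  propagate_copies(out)
}

# Give each lower copy the category/form/features of its antecedent, so that
# all occurrences of one chain are featurally identical.
propagate_copies <- function(t) {
  chains <- new.env(parent = emptyenv())
  collect <- function(x) {
    if (!is.na(x$copy_index) && !x$lower)
      assign(as.character(x$copy_index), x, envir = chains)
    if (is_branch(x)) { collect(x$left); collect(x$right) }
  }
  collect(t)
  fill <- function(x) {
    if (x$lower && !is.na(x$copy_index)) {
      key <- as.character(x$copy_index)
      if (exists(key, envir = chains)) {
        ante <- get(key, envir = chains)
        if (is_leaf(x)) {
          x$features <- if (is_leaf(ante)) ante$features else character()
        }
      }
    }
    if (is_branch(x)) { x$left <- fill(x$left); x$right <- fill(x$right) }
    x
  }
  fill(t)
}

#' Write labeled bracket notation
#'
#' Inverse of [parse_bracketed()] up to whitespace normalization.
#'
#' @param t A `syntactic_object`.
#' @param compact_copies Logical; if `TRUE`, any lower copy (including a full
#'   phrasal copy produced by [merge_internal()]) is rendered as the trace
#'   abbreviation `[<Cat>#i]`.
#' @return A single string.
#' @export
write_bracketed <- function(t, compact_copies = FALSE) {
  stopifnot(inherits(t, "syntactic_object"))
  idx_suffix <- function(x) if (!is.na(x$copy_index)) paste0("#", x$copy_index) else ""
  rec <- function(x) {
    if (x$lower && (compact_copies || is_leaf(x))) {
      cat <- node_symbol(x)
      return(sprintf("[<%s>#%d]", cat, x$copy_index))
    }
    if (is_leaf(x)) {
      inner <- x$category
      if (!is.na(x$form)) inner <- paste(inner, x$form)
      if (length(x$features)) inner <- paste(inner, paste0("+", x$features, collapse = " "))
      return(paste0("[", inner, "]", idx_suffix(x)))
    }
    lab <- if (is.na(x$label)) "" else x$label
    if (x$lower) lab <- paste0("<", lab, ">")
    body <- paste(rec(x$left), rec(x$right))
    if (nzchar(lab)) body <- paste(lab, body)
    paste0("[", body, "]", idx_suffix(x))
  }
  rec(t)
}

## ---------------------------------------------------------------------------
## Geometry
## ---------------------------------------------------------------------------

#' Node count and depth
#'
#' `node_count()` counts every node of the tree: labeled branch nodes
#' (bar levels included) and leaves, silent heads among them. `depth()` is
#' the number of branches on the longest root-to-leaf path, which for this
#' dialect coincides with maximal bracket nesting depth minus one.
#'
#' @param t A `syntactic_object`.
#' @return A non-negative integer.
#' @export
node_count <- function(t) {
  if (is_leaf(t)) 1L else 1L + node_count(t$left) + node_count(t$right)
}

#' @rdname node_count
#' @export
depth <- function(t) {
  if (is_leaf(t)) 0L else 1L + max(depth(t$left), depth(t$right))
}

#' Tree addresses
#'
#' Addresses are root-relative paths, character vectors over
#' `c("left", "right")`; the root is the empty path `character(0)`.
#' `subtree_at()` resolves an address, `all_addresses()` enumerates the
#' addresses of every node in pre-order.
#'
#' @param t A `syntactic_object`.
#' @param address Character vector over `c("left","right")`.
#' @return `subtree_at()`: a `syntactic_object`; `all_addresses()`: a list of
#'   addresses.
#' @export
subtree_at <- function(t, address) {
  for (step in address) {
    if (!is_branch(t)) stop("invalid address: descends below a leaf", call. = FALSE)
    if (!step %in% c("left", "right"))
      stop("invalid address component: ", step, call. = FALSE)
    t <- t[[step]]
  }
  t
}

#' @rdname subtree_at
#' @export
all_addresses <- function(t) {
  out <- list(character(0))
  if (is_branch(t)) {
    out <- c(out,
             lapply(all_addresses(t$left), function(a) c("left", a)),
             lapply(all_addresses(t$right), function(a) c("right", a)))
  }
  out
}

is_valid_address <- function(t, address) {
  !inherits(try(subtree_at(t, address), silent = TRUE), "try-error")
}

is_prefix <- function(a, b) {
  length(a) <= length(b) && identical(as.character(b[seq_along(a)]), as.character(a))
}

#' Dominance and c-command
#'
#' `dominates(t, a, b)` is `TRUE` iff the node at `a` properly dominates the
#' node at `b` (a node does not dominate itself). `c_command(t, a, b)` is
#' `TRUE` iff `a`'s sister dominates or equals `b`, and `a` does not
#' dominate `b` (the "sister-of" derivation of c-command).
#'
#' @param t A `syntactic_object`.
#' @param a,b Addresses (see [subtree_at()]).
#' @return Logical scalar.
#' @export
dominates <- function(t, a, b) {
  stopifnot(is_valid_address(t, a), is_valid_address(t, b))
  is_prefix(a, b) && length(a) < length(b)
}

#' @rdname dominates
#' @export
c_command <- function(t, a, b) {
  stopifnot(is_valid_address(t, a), is_valid_address(t, b))
  if (length(a) == 0L) return(FALSE)   # root has no sister
  sister <- a
  sister[length(a)] <- if (a[length(a)] == "left") "right" else "left"
  (is_prefix(sister, b)) && !is_prefix(a, b)
}

sister_address <- function(a) {
  if (length(a) == 0L) return(NULL)
  a[length(a)] <- if (a[length(a)] == "left") "right" else "left"
  a
}

#' Structural equality of syntactic objects
#'
#' Node-by-node identity of two trees: kinds, categories, forms, feature
#' sets and labels must all agree. With `ignore_copy_marks = TRUE` the copy
#' bookkeeping (copy index and lower-copy flag) is disregarded, the notion
#' of identity used by [check_no_tampering()]: a re-merged occurrence is
#' the same object as its antecedent.
#'
#' @param x,y `syntactic_object`s.
#' @param ignore_copy_marks Logical; see above.
#' @return Logical scalar.
#' @export
so_equal <- function(x, y, ignore_copy_marks = FALSE) {
  if (!identical(x$kind, y$kind)) return(FALSE)
  if (!ignore_copy_marks &&
      (!identical(x$copy_index, y$copy_index) || !identical(x$lower, y$lower)))
    return(FALSE)
  if (is_leaf(x)) {
    identical(x$category, y$category) && identical(x$form, y$form) &&
      setequal(x$features, y$features)
  } else {
    identical(x$label, y$label) &&
      so_equal(x$left, y$left, ignore_copy_marks) &&
      so_equal(x$right, y$right, ignore_copy_marks)
  }
}

# all subtrees (as list of addresses), pre-order
find_nodes <- function(t, pred) {
  Filter(function(a) isTRUE(pred(subtree_at(t, a))), all_addresses(t))
}

#' Locate leaves
#'
#' Convenience search over a tree: addresses of leaves satisfying a
#' predicate, in pre-order (left-to-right surface order).
#'
#' @param t A `syntactic_object`.
#' @param pred Function from node to logical.
#' @return List of addresses.
#' @export
find_leaves <- function(t, pred = function(x) TRUE) {
  find_nodes(t, function(x) is_leaf(x) && isTRUE(pred(x)))
}
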