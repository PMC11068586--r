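# Minimal search (probe-goal), Relativised Minimality, labeling, movement
# paths, and the calibrated step-counting convention.

#' Construct a probe
#'
#' A probe is a searching head (for instance interrogative C carrying
#' `[+Q]`) identified by its address, together with the feature set it
#' seeks.
#'
#' @param origin Address of the probing head (see [subtree_at()]).
#' @param sought Character vector of sought feature names (e.g. `"Q"`).
#' @return A `probe` object.
#' @export
probe <- function(origin, sought) {
  stopifnot(length(sought) >= 1L)
  structure(list(origin = origin, sought = unique(as.character(sought))),
            class = "probe")
}

feature_match <- function(node, sought) {
  is_leaf(node) && all(sought %in% node$features)
}

# Labels of the nodes from `from` (inclusive) down to `to` (inclusive);
# `from` must dominate-or-equal `to`.
path_labels_of <- function(t, from, to) {
  n <- length(to) - length(from) + 1L
  addrs <- vector("list", n)
  for (k in seq_len(n)) addrs[[k]] <- to[seq_len(length(from) + k - 1L)]
  vapply(addrs, function(a) {
    s <- node_symbol(subtree_at(t, a))
    if (is.na(s)) "_" else s
  }, "")
}

#' Minimal search
#'
#' Breadth-first, least-embedding-first search of the probe's c-command
#' domain (its sister's subtree) for a feature-matching goal; at equal depth
#' the left daughter is searched before the right. Ties at the minimal depth
#' are all returned (`goals`); downstream comparison treats equally shallow
#' goals as jointly available.
#'
#' The step count follows the calibrated convention: every node on the path
#' from the probe's sister (inclusive) down to the goal (inclusive) counts
#' as one step; the probe's own projections are not counted.
#'
#' @param t A `syntactic_object`.
#' @param prb A [probe()].
#' @return A `search_result`: `goal` (address or `NULL`), `goals` (all
#'   minimal-depth matches), `path_labels` (symbols from the probe's sister
#'   to the goal), `steps`, `origin_label` (label of the probe's maximal
#'   projection, used by the search-path encoder), and `visited` (number of
#'   nodes examined; equals `steps` on success, all nodes exhausted on
#'   failure).
#' @export
minimal_search <- function(t, prb) {
  stopifnot(inherits(prb, "probe"), is_valid_address(t, prb$origin))
  dom <- sister_address(prb$origin)
  origin_label <- if (length(prb$origin))
    node_symbol(subtree_at(t, prb$origin[-length(prb$origin)])) else node_symbol(t)
  empty <- structure(list(goal = NULL, goals = list(),
                          path_labels = character(0), steps = 0L,
                          origin_label = origin_label, visited = 0L),
                     class = "search_result")
  if (is.null(dom) || !is_valid_address(t, dom)) return(empty)

  queue <- list(dom)
  found <- list(); found_depth <- NA_integer_; visited <- 0L
  while (length(queue)) {
    a <- queue[[1L]]; queue <- queue[-1L]
    if (!is.na(found_depth) && length(a) > found_depth) break
    node <- subtree_at(t, a)
    visited <- visited + 1L
    if (feature_match(node, prb$sought)) {
      found <- c(found, list(a))
      found_depth <- length(a)
    } else if (is_branch(node)) {
      queue <- c(queue, list(c(a, "left")), list(c(a, "right")))
    }
  }
  if (!length(found)) { empty$visited <- visited; return(empty) }
  goal <- found[[1L]]
  labels <- path_labels_of(t, dom, goal)
  structure(list(goal = goal, goals = found, path_labels = labels,
                 steps = length(labels), origin_label = origin_label,
                 visited = length(labels)),
            class = "search_result")
}

#' Search to a designated goal
#'
#' Like [minimal_search()] but with the goal imposed, used to score the
#' path a *dispreferred* association would require (for instance forcing
#' the probe past the matrix verb into a relative clause).
#'
#' @param t A `syntactic_object`.
#' @param prb A [probe()].
#' @param goal Address of the imposed goal.
#' @return A `search_result` (see [minimal_search()]).
#' @export
search_to <- function(t, prb, goal) {
  stopifnot(inherits(prb, "probe"), is_valid_address(t, goal))
  dom <- sister_address(prb$origin)
  origin_label <- if (length(prb$origin))
    node_symbol(subtree_at(t, prb$origin[-length(prb$origin)])) else node_symbol(t)
  if (is.null(dom) || !is_prefix(dom, goal)) {
    # degenerate: goal outside the probe's c-command domain (e.g. the root)
    return(structure(list(goal = goal, goals = list(goal),
                          path_labels = character(0), steps = 0L,
                          origin_label = origin_label, visited = 0L),
                     class = "search_result"))
  }
  labels <- path_labels_of(t, dom, goal)
  structure(list(goal = goal, goals = list(goal), path_labels = labels,
                 steps = length(labels), origin_label = origin_label,
                 visited = length(labels)),
            class = "search_result")
}

#' Tree-search depth
#'
#' Number of nodes searched from the probe down to a goal under the
#' calibrated counting convention: every node on the path from the probe's
#' sister (inclusive) to the goal (inclusive), bar levels and silent heads
#' included. `count_goal` and `count_domain_root` expose the neighbouring
#' conventions for sensitivity checks.
#'
#' @param t A `syntactic_object`.
#' @param prb A [probe()].
#' @param goal Goal address; the degenerate goal-at-root case yields 0.
#' @param count_goal,count_domain_root Convention flags (defaults are the
#'   calibrated convention).
#' @return Non-negative integer.
#' @export
search_depth <- function(t, prb, goal, count_goal = TRUE,
                         count_domain_root = TRUE) {
  res <- search_to(t, prb, goal)
  n <- res$steps
  if (!count_goal && n > 0L) n <- n - 1L
  if (!count_domain_root && n > 0L) n <- n - 1L
  n
}

#' Relativised Minimality
#'
#' A probe-goal relation is blocked if some element Z intervenes (the probe
#' c-commands Z and Z c-commands the goal) and Z fully matches the featural
#' specification of the relation: Z's features are a superset of the
#' probe's sought features *and* of the goal's own features. An intervener
#' featurally poorer than the goal does not block it; occurrences of the
#' goal's own movement chain are not interveners.
#'
#' @param t A `syntactic_object`.
#' @param prb A [probe()]; its origin must c-command the goal.
#' @param goal Address of the goal.
#' @return List with `licensed` (logical), `intervener` (address or
#'   `NULL`) and `interveners` (all blocking addresses).
#' @export
rm_check <- function(t, prb, goal) {
  stopifnot(inherits(prb, "probe"), is_valid_address(t, goal))
  if (!c_command(t, prb$origin, goal))
    stop("probe does not c-command the goal", call. = FALSE)
  goal_node <- subtree_at(t, goal)
  goal_feats <- if (is_leaf(goal_node)) goal_node$features else character(0)
  blockers <- Filter(function(a) {
    if (identical(a, goal)) return(FALSE)
    z <- subtree_at(t, a)
    if (!is_leaf(z) || !length(z$features)) return(FALSE)
    if (!is.na(z$copy_index) && !is.na(goal_node$copy_index) &&
        z$copy_index == goal_node$copy_index) return(FALSE)
    c_command(t, prb$origin, a) && c_command(t, a, goal) &&
      all(prb$sought %in% z$features) && all(goal_feats %in% z$features)
  }, all_addresses(t))
  list(licensed = length(blockers) == 0L,
       intervener = if (length(blockers)) blockers[[1L]] else NULL,
       interveners = blockers)
}

#' Labeling by minimal search
#'
#' Determines the categorial label of a merged set from its most prominent
#' element: a head-phrase pair is labeled by the head's category
#' (head-complement sets are labelable immediately after MERGE); in a
#' phrase-phrase pair a lower copy is invisible to labeling, so the set is
#' labeled from the other member; for two full phrases the label is a
#' shared sought feature if one is supplied, otherwise `NA` (unlabeled, as
#' for adjunction).
#'
#' @param branch A branch `syntactic_object`.
#' @param shared_feature Optional feature name to use as the label of a
#'   phrase-phrase set when both members carry it.
#' @return A categorial symbol, or `NA_character_`.
#' @export
label_of <- function(branch, shared_feature = NULL) {
  stopifnot(is_branch(branch))
  l <- branch$left; r <- branch$right
  head_cat <- function(x) if (is_leaf(x)) x$category else NA_character_
  derived_label <- function(x) {
    if (is_leaf(x)) return(x$category)
    if (!is.na(x$label)) return(x$label)
    label_of(x, shared_feature)
  }
  l_head <- is_leaf(l) && !l$lower
  r_head <- is_leaf(r) && !r$lower
  if (l_head && !r_head) return(head_cat(l))
  if (r_head && !l_head) return(head_cat(r))
  if (l_head && r_head) return(head_cat(l))   # {H, H}: left-prominent
  if (l$lower && !r$lower) return(derived_label(r))
  if (r$lower && !l$lower) return(derived_label(l))
  if (!is.null(shared_feature)) return(shared_feature)
  NA_character_
}

#' Movement path of a chain
#'
#' Addresses of all occurrences sharing a copy index, ordered from the most
#' deeply embedded (the initially merged, base position) through
#' intermediate landing sites to the terminal landing site.
#'
#' @param t A `syntactic_object`.
#' @param copy_index Integer chain index; the chain must have at least two
#'   occurrences.
#' @return List of addresses, base first.
#' @export
movement_path <- function(t, copy_index) {
  idx <- as.integer(copy_index)
  sites <- find_nodes(t, function(x) !is.na(x$copy_index) && x$copy_index == idx)
  if (length(sites) < 2L)
    stop("copy index ", idx, " has fewer than 2 occurrences: not a movement chain",
         call. = FALSE)
  sites[order(-vapply(sites, length, 0L))]
}
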