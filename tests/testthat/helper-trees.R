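# Random tree generation for property-style tests.

random_tree <- function(n_leaves, categories = c("C", "T", "V", "N", "D", "P"),
                        p_form = 0.6, p_feature = 0.3) {
  random_leaf <- function() {
    cat <- sample(categories, 1L)
    form <- if (stats::runif(1) < p_form)
      paste0(sample(letters, 3L, replace = TRUE), collapse = "") else NULL
    feats <- if (stats::runif(1) < p_feature)
      sample(c("Q", "N", "Foc"), sample(1:2, 1L)) else character()
    so_leaf(cat, form = form, features = feats)
  }
  build <- function(k) {
    if (k == 1L) return(random_leaf())
    kl <- sample.int(k - 1L, 1L)
    lab <- if (stats::runif(1) < 0.85)
      paste0(sample(categories, 1L), sample(c("", "P", "'"), 1L)) else NULL
    so_branch(build(kl), build(k - kl), label = lab)
  }
  build(n_leaves)
}

# all binary tree shapes with exactly n leaves, deterministic labels
all_tree_shapes <- function(n_leaves) {
  if (n_leaves == 1L) return(list(so_leaf("N", "x")))
  out <- list()
  for (kl in seq_len(n_leaves - 1L)) {
    for (lt in all_tree_shapes(kl)) for (rt in all_tree_shapes(n_leaves - kl))
      out[[length(out) + 1L]] <- so_branch(lt, rt, label = "V")
  }
  out
}

random_symbols <- function(n, alphabet_size) {
  as.character(sample.int(alphabet_size, n, replace = TRUE))
}

# exhaustive strings of given length over 1..alpha as character symbols
all_strings <- function(len, alpha) {
  grid <- do.call(expand.grid, rep(list(seq_len(alpha)), len))
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}
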