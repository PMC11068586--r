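test_that("node/terminal serialization matches the printed enumeration", {
  cfg <- encoding_config("node_terminal")
  s2b <- encode_node_terminal(tcc_fixture("ex2b"), cfg)
  expect_identical(s2b$symbols, c("a", "l", "a", "b", "g", "d", "e"))
  s2c <- encode_node_terminal(tcc_fixture("ex2c"), cfg)
  expect_identical(s2c$symbols, c("a", "b", "g", "d", "e", "e", "l"))
  expect_identical(encode_node_terminal(so_leaf("N", "x"))$symbols, "N")
  # unlabeled branches contribute the category-less marker
  unl <- so_branch(so_leaf("N", "x"), so_leaf("V", "y"))
  expect_identical(encode_node_terminal(unl, cfg)$symbols, c("_", "N", "V"))
  # sequence length = branch-label count + terminal count
  set.seed(31)
  for (k in seq_len(100)) {
    t <- random_tree(sample(1:8, 1L))
    expect_identical(length(encode_node_terminal(t, cfg)$symbols),
                     node_count(t))
  }
})

test_that("search-path serialization covers nodes and transitions policies", {
  t6 <- tcc_fixture("ex6b")
  pr <- probe(find_leaves(t6, function(x) x$category == "C")[[1L]], "V")
  res_v <- minimal_search(t6, pr)
  rhyme <- find_leaves(t6, function(x) identical(x$form, "rhyme"))[[1L]]
  res_tp <- search_to(t6, pr, rhyme)
  nodes_cfg <- encoding_config("search_path", step_symbols = "nodes")
  expect_identical(encode_search_path(res_v, nodes_cfg)$symbols,
                   c("CP", "TP", "T'", "V"))
  expect_identical(encode_search_path(res_tp, nodes_cfg)$symbols,
                   c("CP", "TP", "DP", "CP", "TP"))
  trans_cfg <- encoding_config("search_path", step_symbols = "transitions")
  expect_identical(encode_search_path(res_v, trans_cfg)$symbols,
                   c("CP", "TP", "TP", "T'", "T'", "V"))
  expect_identical(encode_search_path(res_tp, trans_cfg)$symbols,
                   c("CP", "TP", "TP", "DP", "DP", "CP", "CP", "TP"))
  # per-category policy collapses bar levels and phrases
  cat_cfg <- encoding_config("search_path", symbol_policy = "per_category",
                             step_symbols = "nodes")
  expect_identical(encode_search_path(res_v, cat_cfg)$symbols,
                   c("C", "T", "T", "V"))
  # an empty path cannot be encoded
  t <- parse_bracketed("[VP [V see] [DP them]]")
  expect_error(encode_search_path(minimal_search(t, probe("left", "Q"))),
               "no goal")
})

test_that("movement-path serialization gives one symbol per site", {
  t9a <- tcc_fixture("ex9a"); t9b <- tcc_fixture("ex9b")
  cfg <- encoding_config("movement_path")
  expect_identical(encode_movement_path(movement_path(t9a, 1L), t9a, cfg)$symbols,
                   c("V'", "TP", "VP", "CP"))
  expect_identical(encode_movement_path(movement_path(t9b, 1L), t9b, cfg)$symbols,
                   c("VP", "TP", "VP", "CP"))
  # trivial two-site movement
  ws <- merge_internal(workspace(roots = list(
    parse_bracketed("[VP [V see] [DP them]]"))), 1L, "right", label = "CP")
  p <- movement_path(ws$roots[[1L]], 1L)
  expect_identical(encode_movement_path(p, ws$roots[[1L]], cfg)$symbols,
                   c("VP", "CP"))
  expect_error(encode_movement_path(p[1L], ws$roots[[1L]], cfg), "2 sites")
})

test_that("phrase-label serialization walks terminal phrase units left-to-right", {
  cfg <- encoding_config("label_sequence", symbol_policy = "per_category")
  expect_identical(encode_label_sequence(tcc_fixture("ex13a"), cfg)$symbols,
                   c("V", "D", "P", "D", "V"))
  expect_identical(encode_label_sequence(tcc_fixture("ex13b"), cfg)$symbols,
                   c("D", "V", "D", "P", "D", "V"))
  invis <- encoding_config("label_sequence", symbol_policy = "per_category",
                           copy_policy = "invisible")
  expect_identical(encode_label_sequence(tcc_fixture("ex13b"), invis)$symbols,
                   c("D", "V", "P", "V"))
  expect_identical(encode_label_sequence(so_leaf("V", "ran"))$symbols, "V")
})

test_that("encoders are deterministic and equivariant under relabeling", {
  t9a <- tcc_fixture("ex9a")
  cfg <- tcc_default_config("node_terminal")
  s1 <- encode_node_terminal(t9a, cfg)
  s2 <- encode_node_terminal(tcc_fixture("ex9a"), cfg)
  expect_identical(s1$symbols, s2$symbols)
  # bijective relabeling permutes symbols without changing the parse
  set.seed(5)
  for (k in seq_len(50)) {
    t <- random_tree(sample(2:7, 1L))
    s <- encode_node_terminal(t, cfg)
    perm <- sample(s$alphabet)
    names(perm) <- s$alphabet
    relabeled <- unname(perm[s$symbols])
    expect_identical(lz76_phrase_count(relabeled),
                     lz76_phrase_count(s$symbols))
  }
})

test_that("binary recodings preserve decodability width conventions", {
  s <- symbol_sequence(c("a", "b", "a", "c"))
  expect_identical(paste(binarize_sequence(s, "fixed")$symbols, collapse = ""),
                   "00010010")
  expect_identical(paste(binarize_sequence(s, "fixed1")$symbols, collapse = ""),
                   "01100111")
  expect_identical(paste(binarize_sequence(s, "minwidth")$symbols, collapse = ""),
                   "01010")
  expect_identical(binarize_sequence(s, "none"), s)
  expect_setequal(binarize_sequence(s, "minwidth1")$alphabet, c("0", "1"))
})

test_that("sequences serialize to a provenance-carrying TSV", {
  seqs <- list(a = encode_node_terminal(tcc_fixture("ex2b")),
               b = encode_node_terminal(tcc_fixture("ex2c")))
  path <- tempfile(fileext = ".tsv")
  df <- sequences_to_tsv(seqs, path)
  expect_true(file.exists(path))
  back <- utils::read.delim(path)
  expect_identical(back$n, c(7L, 7L))
  expect_identical(back$provenance, rep("node_terminal", 2L))
  unlink(path)
})
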