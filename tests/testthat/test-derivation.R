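lex_xyz <- function() list(x = lex_item("N", "x"), y = lex_item("N", "y"),
                           z = lex_item("N", "z"))

test_that("external merge forms {Z, {X, Y}} and embeds operands unchanged", {
  ws <- workspace(lex_xyz(), roots = list(lex_item("N", "y")))
  ws1 <- merge_external(ws, "x", 1L)            # {x, y}
  expect_length(ws1$roots, 1L)
  expect_identical(node_count(ws1$roots[[1L]]), 3L)
  ws2 <- merge_external(ws1, "z", 1L)           # {z, {x, y}}
  r <- ws2$roots[[1L]]
  expect_true(is_branch(r))
  expect_identical(r$left$form, "z")
  expect_true(so_equal(r$right, ws1$roots[[1L]]))
  expect_error(merge_external(ws, "x", 5L), "not a root")
})

test_that("merging lambda at the root of (2a) yields (2b)", {
  ws <- workspace(list(l = lex_item("l")), roots = list(tcc_fixture("ex2a")))
  ws1 <- merge_external(ws, "l", 1L, label = "a")
  expect_true(so_equal(ws1$roots[[1L]], tcc_fixture("ex2b")))
})

test_that("internal merge produces a marked copy chain without tampering", {
  ws <- workspace(roots = list(parse_bracketed("[VP [V see] [DP them]]")))
  ws1 <- merge_internal(ws, 1L, c("right"), label = "CP")
  r <- ws1$roots[[1L]]
  expect_identical(r$label, "CP")
  expect_identical(r$left$copy_index, 1L)
  expect_false(r$left$lower)
  expect_true(subtree_at(r, c("right", "right"))$lower)
  expect_true(check_no_tampering(last_step(ws1))$pass)
  expect_error(merge_internal(ws, 1L, character(0)), "excluded")
  expect_error(merge_internal(ws, 1L, c("left", "left", "left")), "invalid address")
})

test_that("raising the subject of the in-situ structure gives the raised geometry", {
  t13a <- tcc_fixture("ex13a")
  ws <- workspace(roots = list(t13a))
  target <- find_leaves(t13a, function(x) identical(x$form, "the_student") &&
                          !x$lower)[[1L]]
  ws1 <- merge_internal(ws, 1L, target, label = "d")
  got <- write_bracketed(ws1$roots[[1L]], compact_copies = TRUE)
  expect_identical(got, paste0(
    "[d [D the_student]#2 [g [V seems_to_be_likely] [a [<D>#2] ",
    "[P' [P to] [V' [<D>#1] [V understand_the_theory]]]]]]"))
  # same landing-site geometry as the raised fixture: the new chain sits in
  # the d-spec with its copy in the a-spec, as in ex13b's top two sites
  parent_label <- function(t, a) subtree_at(t, a[-length(a)])$label
  t13b <- tcc_fixture("ex13b")
  sites13b <- movement_path(t13b, 1L)
  sites_new <- movement_path(ws1$roots[[1L]], 2L)
  expect_identical(parent_label(ws1$roots[[1L]], sites_new[[2L]]), "d")
  expect_identical(parent_label(t13b, sites13b[[3L]]), "d")
  expect_identical(parent_label(ws1$roots[[1L]], sites_new[[1L]]), "a")
  expect_identical(parent_label(t13b, sites13b[[2L]]), "a")
})

test_that("No Tampering distinguishes root extension from internal modification", {
  ws0 <- workspace(list(l = lex_item("l")), roots = list(tcc_fixture("ex2a")))
  ws_b <- merge_external(ws0, "l", 1L, label = "a")
  expect_true(check_no_tampering(last_step(ws_b))$pass)
  tampered <- list(before = ws0,
                   after = workspace(roots = list(tcc_fixture("ex2c"))))
  res <- check_no_tampering(tampered)
  expect_false(res$pass)
  expect_identical(res$witness, "right")     # the gamma set was broken into
  identity_step <- list(before = ws0, after = ws0)
  expect_true(check_no_tampering(identity_step)$pass)
})

test_that("workspace size is accessible terms plus syntactic objects", {
  expect_identical(workspace_size(workspace()), 0L)
  ws <- workspace(roots = list(parse_bracketed("[[N x] [N y]]")))
  expect_identical(accessible_terms(ws), 3L)    # X, Y, {X,Y}
  expect_identical(workspace_size(ws), 4L)
  expect_identical(workspace_size(ws, count_root_as_term = FALSE), 3L)
  # lower copies are the same object and are counted once
  ws1 <- merge_internal(ws, 1L, "left")
  expect_identical(accessible_terms(ws1), 4L)   # x, y, {x,y}, {x,{x,y}}
})

test_that("Resource Restriction passes engine steps and flags duplication", {
  ws <- workspace(lex_xyz(), roots = list(lex_item("N", "y")))
  ws1 <- merge_external(ws, "x", 1L)
  expect_true(check_resource_restriction(last_step(ws1))$pass)
  ws2 <- merge_internal(ws1, 1L, "left")
  expect_true(check_resource_restriction(last_step(ws2))$pass)
  # a hypothetical non-MERGE step duplicating two roots into the workspace
  dup <- list(before = ws1,
              after = workspace(roots = c(ws1$roots, ws1$roots)))
  expect_false(check_resource_restriction(dup)$pass)
})

test_that("every step of seeded random derivations satisfies the economy checks", {
  set.seed(99)
  for (k in seq_len(200)) {
    ws <- workspace(lex_xyz(), roots = list(lex_item("N", "seed")))
    snapshot <- ws
    for (s in seq_len(sample(2:5, 1L))) {
      if (length(ws$roots) && stats::runif(1) < 0.35 &&
          is_branch(ws$roots[[1L]])) {
        addrs <- all_addresses(ws$roots[[1L]])
        addrs <- Filter(function(a) length(a) > 0L &&
                          !subtree_at(ws$roots[[1L]], a)$lower, addrs)
        if (length(addrs)) {
          ws <- merge_internal(ws, 1L, addrs[[sample.int(length(addrs), 1L)]])
          next
        }
      }
      ws <- merge_external(ws, sample(names(ws$lexicon), 1L), 1L)
    }
    for (st in ws$history) {
      expect_true(check_no_tampering(st)$pass)
      expect_true(check_resource_restriction(st)$pass)
    }
    # inputs were never mutated
    expect_true(so_equal(snapshot$roots[[1L]], lex_item("N", "seed")))
  }
})

test_that("the Markov property holds for coincident workspaces", {
  lx <- list(a = lex_item("N", "a"), b = lex_item("N", "b"),
             c = lex_item("N", "c"), d = lex_item("N", "d"))
  # two orders of building the same two sets from four items
  w0 <- workspace(lx, roots = list(lx$a, lx$c))
  h1 <- merge_external(merge_external(w0, "b", 1L), "d", 1L)
  h2 <- merge_external(merge_external(w0, "d", 2L), "b", 1L)
  expect_identical(canonical_workspace(h1), canonical_workspace(h2))
  expect_true(markov_check(h1, h2))
  # unequal workspaces are a precondition error
  h3 <- merge_external(w0, "b", 2L)
  expect_error(markov_check(h1, h3), "equal workspaces")
})

test_that("derivation scripts replay deterministically with a JSON log", {
  lines <- c("# build {z, {x, y}} and raise x",
             "EM y 1", "EM x 1", "EM z 1 VP", "IM 1 rl DP")
  ws <- replay_script(lines, lex_xyz())
  expect_length(ws$roots, 1L)
  expect_identical(ws$roots[[1L]]$label, "DP")
  log <- jsonlite::fromJSON(derivation_log(ws), simplifyVector = FALSE)
  expect_length(log, 3L)
  expect_true(all(vapply(log, function(s) isTRUE(s$no_tampering), TRUE)))
  expect_true(all(vapply(log, function(s) isTRUE(s$resource_restriction), TRUE)))
  ws2 <- replay_script(lines, lex_xyz())
  expect_identical(canonical_workspace(ws), canonical_workspace(ws2))
})
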