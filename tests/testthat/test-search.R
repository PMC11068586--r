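probe_at_C <- function(t, sought, form = NULL) {
  pred <- if (is.null(form)) function(x) x$category == "C"
          else function(x) identical(x$form, form)
  probe(find_leaves(t, pred)[[1L]], sought)
}

test_that("minimal search finds the least-embedded verbal goal in three steps", {
  t6 <- tcc_fixture("ex6b")
  res <- minimal_search(t6, probe_at_C(t6, "V"))
  expect_identical(subtree_at(t6, res$goal)$form, "evaporate")
  expect_identical(res$steps, 3L)
  expect_identical(res$path_labels, c("TP", "T'", "V"))
  expect_identical(res$origin_label, "CP")
})

test_that("forcing the probe into the relative clause costs four node steps", {
  t6 <- tcc_fixture("ex6b")
  rhyme <- find_leaves(t6, function(x) identical(x$form, "rhyme"))[[1L]]
  res <- search_to(t6, probe_at_C(t6, "V"), rhyme)
  expect_identical(res$steps, 4L)
  expect_identical(res$path_labels, c("TP", "DP", "CP", "TP"))
})

test_that("a probe over an exhausted domain returns no goal", {
  t <- parse_bracketed("[VP [V see] [DP them]]")
  res <- minimal_search(t, probe(c("left"), "Q"))
  expect_null(res$goal)
  expect_identical(res$steps, 0L)
  expect_identical(res$visited, 1L)          # the single sister node examined
})

test_that("tree-search depth of the wh-extraction pair is 11 versus 9", {
  t9a <- tcc_fixture("ex9a"); t9b <- tcc_fixture("ex9b")
  d_a <- search_depth(t9a, probe_at_C(t9a, "Q", form = "did"),
                      movement_path(t9a, 1L)[[1L]])
  d_b <- search_depth(t9b, probe_at_C(t9b, "Q", form = "did"),
                      movement_path(t9b, 1L)[[1L]])
  expect_identical(d_a, 11L)
  expect_identical(d_b, 9L)
  # degenerate goal at the root
  expect_identical(search_depth(t9a, probe_at_C(t9a, "Q", form = "did"),
                                character(0)), 0L)
})

test_that("Relativised Minimality blocks across a featurally richer intervener", {
  t3a <- tcc_fixture("ex3a")
  res_a <- rm_check(t3a, probe_at_C(t3a, "Q", form = "do"),
                    movement_path(t3a, 1L)[[1L]])
  expect_false(res_a$licensed)
  expect_identical(subtree_at(t3a, res_a$intervener)$form, "which_game")
  t3b <- tcc_fixture("ex3b")
  res_b <- rm_check(t3b, probe_at_C(t3b, "Q", form = "do"),
                    movement_path(t3b, 1L)[[1L]])
  expect_true(res_b$licensed)
  # no intervener at all
  t <- parse_bracketed("[CP [C do +Q] [TP [DP you] [VP [V saw] [DP who +Q]]]]")
  res <- rm_check(t, probe_at_C(t, "Q"),
                  find_leaves(t, function(x) identical(x$form, "who"))[[1L]])
  expect_true(res$licensed)
  who <- find_leaves(t, function(x) identical(x$form, "who"))[[1L]]
  you <- find_leaves(t, function(x) identical(x$form, "you"))[[1L]]
  expect_error(rm_check(t, probe(who, "Q"), you), "c-command")
})

test_that("rm_check is monotone: enriching an intervener never unblocks", {
  set.seed(7)
  base <- "[CP [C p +Q] [TP [DP z %s] [VP [V v] [DP goal +Q %s]]]]"
  feature_pool <- c("Q", "N", "Foc")
  for (k in seq_len(50)) {
    gf <- sample(feature_pool, sample(1:2, 1L))
    zf <- sample(feature_pool, sample(0:3, 1L) + 0L)
    mk <- function(zfeats) {
      parse_bracketed(sprintf(base,
                              paste(c("", paste0("+", zfeats)), collapse = " "),
                              paste(c("", paste0("+", gf)), collapse = " ")))
    }
    t0 <- mk(zf)
    goal <- find_leaves(t0, function(x) identical(x$form, "goal"))[[1L]]
    r0 <- rm_check(t0, probe_at_C(t0, "Q"), goal)
    extra <- setdiff(feature_pool, zf)
    if (!length(extra)) next
    t1 <- mk(c(zf, sample(extra, 1L)))
    r1 <- rm_check(t1, probe_at_C(t1, "Q"), goal)
    if (!r0$licensed) expect_false(r1$licensed)
  }
})

test_that("labeling follows prominence and ignores lower copies", {
  h_phrase <- so_branch(so_leaf("V", "see"),
                        so_branch(so_leaf("D", "the"), so_leaf("N", "dog"), "DP"))
  expect_identical(label_of(h_phrase), "V")       # {head, phrase}: head labels
  hc <- parse_bracketed("[[V see] [DP them]]")
  expect_identical(label_of(hc), "V")             # head-complement, at once
  xp_yp <- so_branch(parse_bracketed("[DP [D the] [N dog]]"),
                     parse_bracketed("[VP [V ran] [P off]]"))
  expect_true(is.na(label_of(xp_yp)))
  expect_identical(label_of(xp_yp, shared_feature = "Q"), "Q")
  # {XP, YP} with XP a lower copy: labeled from YP
  low <- so_branch(so_leaf("D", copy_index = 3L, lower = TRUE),
                   parse_bracketed("[VP [V ran] [P off]]"))
  expect_identical(label_of(low), "VP")
})

test_that("movement paths enumerate base, intermediate and terminal sites", {
  t9a <- tcc_fixture("ex9a"); t9b <- tcc_fixture("ex9b")
  p_a <- movement_path(t9a, 1L); p_b <- movement_path(t9b, 1L)
  expect_length(p_a, 4L)
  expect_length(p_b, 4L)
  parent_label <- function(t, a) subtree_at(t, a[-length(a)])$label
  expect_identical(vapply(p_a, parent_label, "", t = t9a),
                   c("V'", "TP", "VP", "CP"))
  expect_identical(vapply(p_b, parent_label, "", t = t9b),
                   c("VP", "TP", "VP", "CP"))
  # depths strictly decrease from base to terminal site
  expect_true(all(diff(vapply(p_a, length, 0L)) < 0))
  expect_error(movement_path(t9a, 7L), "fewer than 2")
})

test_that("minimal search returns a least-embedded goal on decorated trees", {
  set.seed(11)
  for (k in seq_len(200)) {
    t <- so_branch(so_leaf("C", "c", features = "Q"), random_tree(sample(2:7, 1L)),
                   label = "CP")
    res <- minimal_search(t, probe(c("left"), "Q"))
    matches <- find_leaves(t$right, function(x) "Q" %in% x$features)
    if (!length(matches)) {
      expect_null(res$goal)
    } else {
      min_depth <- min(vapply(matches, length, 0L))
      expect_identical(length(res$goal) - 1L, min_depth)  # relative to sister
      # every tied least-embedded match is reported
      expect_identical(length(res$goals),
                       sum(vapply(matches, length, 0L) == min_depth))
    }
  }
})
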