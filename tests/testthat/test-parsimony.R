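# Generalized Fitch parsimony, MPR state sets, event ranges, oracles.

test_that("minimum change counts match simple expectations", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_count(tr, c(A="UVS", B="UVS", C="VS", D="VS"))$min_changes, 1L)
  expect_equal(fitch_count(tr, c(A="VS", B="VS", C="VS", D="VS"))$min_changes, 0L)
  # star tree with k distinct states needs k - 1 changes
  star <- parse_newick("(A,B,C,D,E);")
  expect_equal(fitch_count(star, c(A="1",B="2",C="3",D="4",E="5"))$min_changes, 4L)
  expect_equal(root_state_set(star, c(A="1",B="1",C="1",D="1",E="1")), "1")
  # 3-tip example with exhaustive-oracle confirmation
  t3 <- parse_newick("((A,B),C);")
  st3 <- c(A="X1", B="X2", C="X1")
  expect_equal(fitch_count(t3, st3)$min_changes, 1L)
  expect_equal(brute_force_min_changes(t3, st3), 1L)
})

test_that("tips without states are dropped with a warning; degenerate input errors", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_warning(fc <- fitch_count(tr, c(A="UVS", B="VS", C="VS")),
                 "dropping")
  expect_equal(fc$dropped_tips, "D")
  expect_equal(fc$min_changes, 1L)
  expect_error(fitch_count(tr, c(Z="UVS")), "no tip has a state")
  expect_error(suppressWarnings(fitch_count(tr, c(A="UVS"))), "at least 2")
})

test_that("DP equals the exhaustive oracle on every small shape and assignment", {
  # all rooted binary shapes on 4 and 5 tips x all 2-state assignments,
  # plus 3-state assignments on 4 tips
  tips4 <- LETTERS[1:4]
  shapes4 <- all_rooted_topologies(tips4)
  for (shape in shapes4) {
    tr <- parse_newick(paste0(shape, ";"))
    for (mask in 0:(2^4 - 1)) {
      st <- stats::setNames(ifelse(bitwAnd(mask, 2^(0:3)) > 0, "U", "V"), tips4)
      expect_equal(fitch_count(tr, st)$min_changes,
                   brute_force_min_changes(tr, st),
                   info = paste(shape, mask))
    }
    grid3 <- expand.grid(rep(list(c("a","b","c")), 4), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid3))) {
      st <- stats::setNames(unlist(grid3[i, ], use.names = FALSE), tips4)
      expect_equal(fitch_count(tr, st)$min_changes,
                   brute_force_min_changes(tr, st))
    }
  }
  tips5 <- LETTERS[1:5]
  for (shape in all_rooted_topologies(tips5)) {
    tr <- parse_newick(paste0(shape, ";"))
    for (mask in 0:(2^5 - 1)) {
      st <- stats::setNames(ifelse(bitwAnd(mask, 2^(0:4)) > 0, "U", "V"), tips5)
      expect_equal(fitch_count(tr, st)$min_changes,
                   brute_force_min_changes(tr, st))
    }
  }
  # polytomies: random 6-tip trees with short internal edges collapsed
  for (i in 1:10) {
    set.seed(100 + i)
    tr <- ape::rtree(6)
    tr2 <- ape::di2multi(tr, tol = stats::quantile(tr$edge.length, 0.5))
    tr2$edge.length <- NULL
    st <- stats::setNames(sample(c("U","V","W"), 6, TRUE), tr2$tip.label)
    expect_equal(fitch_count(tr2, st)$min_changes,
                 brute_force_min_changes(tr2, st))
  }
})

test_that("DP agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    tr <- random_tree(n, seed = 500 + i)
    st <- stats::setNames(sample(c("u", "v"), n, TRUE), tr$tip.label)
    if (length(unique(st)) == 1L) next
    pd <- phangorn::phyDat(as.matrix(st), type = "USER", levels = c("u", "v"))
    expect_equal(fitch_count(tr, st)$min_changes,
                 as.integer(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("event ranges from the DP equal exhaustive MPR enumeration", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    tr <- random_tree(n, seed = 900 + i)
    st <- stats::setNames(sample(c("U", "V"), n, TRUE), tr$tip.label)
    if (length(unique(st)) == 1L) next
    dp <- reconstruct_shifts(tr, st, labeler = labeler_uv_route(),
                             method = "dp")
    en <- reconstruct_shifts(tr, st, labeler = labeler_uv_route(),
                             method = "enumerate")
    expect_equal(dp$event_range, en$event_range, info = paste("tree", i))
    # representative MPR events total the minimum and sit inside the ranges
    expect_equal(nrow(dp$representative_events), dp$min_changes)
    cnt <- table(factor(dp$representative_events$label,
                        levels = dp$event_range$label))
    expect_true(all(as.numeric(cnt) >= dp$event_range$min &
                      as.numeric(cnt) <= dp$event_range$max))
  }
})

test_that("root state set contains exactly the states attainable in MPRs", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    tr <- random_tree(n, seed = 1300 + i)
    st <- stats::setNames(sample(c("U", "V", "W"), n, TRUE), tr$tip.label)
    if (length(unique(st)) == 1L) next
    fc <- fitch_count(tr, st)
    en <- enumerate_mprs(tr, st)
    root_col <- colnames(en$assignments)[1]
    expect_setequal(fc$root_state_set, unique(en$assignments[, 1]))
  }
})

test_that("newick parse/write round-trips and rejects malformed input", {
  s <- "((A,B),(C,D));"
  tr <- parse_newick(s)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  tr2 <- parse_newick(write_newick(tr))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2))), 0)
  expect_error(parse_newick("((A,B);"), "unbalanced")
  expect_error(parse_newick("A,B"), "Newick")
  # packaged tree round-trips with identical topology
  ref <- build_reference_tree()
  back <- parse_newick(write_newick(ref$tree))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref$tree), ape::unroot(back))), 0)
  expect_setequal(back$tip.label, ref$tree$tip.label)
})

test_that("annotated newick carries event tags and stays parseable", {
  tr <- parse_newick("((A,B),(C,D));")
  rec <- reconstruct_shifts(tr, c(A="UVS", B="UVS", C="VS", D="VS"),
                            labeler = labeler_uv_route())
  ann <- write_annotated_newick(rec)
  expect_match(ann, "\\[&shift=")
  back <- parse_newick(ann)
  expect_setequal(back$tip.label, tr$tip.label)
})
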