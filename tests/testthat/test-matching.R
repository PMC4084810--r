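test_that("jaccard index has its defining values", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_index(c("1", "2", "3"), c("2", "3", "4")), 0.5)
  expect_equal(jaccard_index(c("a"), c("a", "b")),
               jaccard_index(c("a", "b"), c("a")))
  expect_error(jaccard_index(character(0), character(0)), "undefined")
})

test_that("identical partitions inherit their twin communities", {
  parts <- partitions_from_groups(list(
    list(c("a", "b", "c"), c("d", "e")),
    list(c("a", "b", "c"), c("d", "e"))))
  tl <- match_groups(parts, jaccard_threshold = 0.4)
  expect_equal(tl$n_communities, 2L)
  expect_equal(tl$community_of_group[[2]], tl$community_of_group[[1]])
})

test_that("threshold matching and new-community creation work as specified", {
  # {a,b,x} vs {a,b,c}: J = 2/4 = 0.5 >= 0.4 -> inherit; {y,z} disjoint ->
  # new community 3
  parts <- partitions_from_groups(list(
    list(c("a", "b", "c"), c("d", "e")),
    list(c("a", "b", "x"), c("y", "z"))))
  tl <- match_groups(parts, jaccard_threshold = 0.4)
  expect_equal(tl$community_of_group[[2]][1], 1L)
  expect_equal(tl$community_of_group[[2]][2], 3L)
  expect_equal(tl$n_communities, 3L)
  expect_equal(unname(tl$membership["x", 2]), 1L)
  expect_true(is.na(tl$membership["x", 1]))
})

test_that("the backward search reaches past t-1", {
  # t=3 group equals a t=1 group; nothing at t=2 clears the threshold
  parts <- partitions_from_groups(list(
    list(c("a", "b", "c", "d")),
    list(c("p", "q", "r")),
    list(c("a", "b", "c", "d"))))
  tl <- match_groups(parts, jaccard_threshold = 0.4)
  expect_equal(tl$community_of_group[[3]][1], 1L)
  # with search_depth = 1 the same group cannot reach t=1: new community
  tl1 <- match_groups(parts, jaccard_threshold = 0.4, search_depth = 1)
  expect_equal(tl1$community_of_group[[3]][1], 3L)
})

test_that("matching within a time point is one-to-one, greedy by Jaccard", {
  # both current groups overlap the same earlier group most strongly; the
  # higher-Jaccard pair wins it, the other falls to its second-best
  parts <- partitions_from_groups(list(
    list(c("a", "b", "c", "d"), c("e", "f")),
    list(c("a", "b", "c"), c("d", "e", "f"))))
  tl <- match_groups(parts, jaccard_threshold = 0.1)
  # J({abc},{abcd}) = 3/4; J({def},{abcd}) = 1/4; J({def},{ef}) = 2/3
  expect_equal(tl$community_of_group[[2]], c(1L, 2L))
})

test_that("zero-Jaccard pairs never match even at threshold 0", {
  parts <- partitions_from_groups(list(
    list(c("a", "b")),
    list(c("x", "y"))))
  tl <- match_groups(parts, jaccard_threshold = 0)
  expect_equal(tl$n_communities, 2L)
})

test_that("degenerate thresholds behave as the theory dictates", {
  parts <- partitions_from_groups(list(
    list(c("a", "b", "c"), c("d", "e")),
    list(c("a", "b"), c("c", "d", "e")),
    list(c("a", "b", "c"), c("d", "e"))))
  # threshold above every achievable Jaccard: one fresh community per group
  tl_hi <- match_groups(parts, jaccard_threshold = 1)
  # identical groups do reach J = 1; use a partition list with no exact
  # repeats to check the fresh-community count
  expect_equal(match_groups(partitions_from_groups(list(
    list(c("a", "b", "c")), list(c("a", "b", "x")),
    list(c("a", "x", "y")))), jaccard_threshold = 1)$n_communities, 3L)
  # identical snapshots at threshold <= 1 keep n_communities = G1
  ident <- partitions_from_groups(list(
    list(c("a", "b"), c("c", "d")),
    list(c("a", "b"), c("c", "d"))))
  expect_equal(match_groups(ident, jaccard_threshold = 1)$n_communities, 2L)
  # at threshold 1 the t=2 groups are fresh (3, 4); the t=3 groups equal
  # their t=1 twins exactly and the deep search recovers communities 1, 2
  expect_equal(tl_hi$n_communities, 4L)
  expect_equal(tl_hi$community_of_group[[3]], c(1L, 2L))
})

test_that("raising the threshold never decreases n_communities here", {
  set.seed(31)
  sim <- synthetic_dynamic_network(
    n_communities = 3, nodes_per_community = 6, n_times = 4,
    p_in = 0.85, p_out = 0.15,
    cohorts = list(list(nodes = 1:3, targets = c(1, 2, 3, 1))),
    p_absent = 0.1, seed = 31)
  parts <- partition_all(sim$network, seed = 31)
  ths <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  ncomm <- vapply(ths, function(th)
    match_groups(parts, jaccard_threshold = th)$n_communities, integer(1))
  expect_true(all(diff(ncomm) >= 0))
})

test_that("greedy matcher equals the brute-force reference matcher", {
  set.seed(41)
  for (rep in 1:12) {
    TT <- sample(2:4, 1)
    groups_per_time <- lapply(seq_len(TT), function(t) {
      ng <- sample(1:4, 1)
      pool <- sample(letters, sample(4:10, 1))
      split(pool, sort(rep_len(seq_len(ng), length(pool))))
    })
    parts <- partitions_from_groups(groups_per_time)
    for (th in c(0.1, 0.3, 0.5)) {
      got <- match_groups(parts, jaccard_threshold = th)
      ref <- brute_force_match(parts, jaccard_threshold = th)
      expect_identical(got$community_of_group, ref$community_of_group)
      expect_identical(got$n_communities, ref$n_communities)
    }
  }
})

test_that("match_groups validates its inputs", {
  parts <- partitions_from_groups(list(list(c("a", "b")), list(c("a", "b"))))
  expect_error(match_groups(parts, jaccard_threshold = 1.5), "\\[0, 1\\]")
  expect_error(match_groups(parts[1]), "at least two")
  bad <- parts; bad[[2]]$time <- 1
  expect_error(match_groups(bad), "distinct")
})

test_that("community_present reflects per-time group support", {
  parts <- partitions_from_groups(list(
    list(c("a", "b", "c"), c("d", "e")),
    list(c("a", "b", "c"))))
  tl <- match_groups(parts, jaccard_threshold = 0.4)
  expect_true(community_present(tl, 1, 1))
  expect_true(community_present(tl, 1, 2))
  expect_true(community_present(tl, 2, 1))
  expect_false(community_present(tl, 2, 2))
  expect_error(community_present(tl, 99, 1), "unknown community")
})
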