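# membership matrices are the natural fixture here: build timelines
# directly and check the DP against exhaustive trajectory enumeration
mk_tl <- function(memb) timeline_from_membership(memb)

test_that("a loyal member of one stable community costs nothing", {
  m <- matrix(1L, nrow = 3, ncol = 4,
              dimnames = list(c("a", "b", "c"), NULL))
  ha <- assign_home(mk_tl(m))
  expect_equal(unname(ha$node_cost), c(0, 0, 0))
  expect_true(all(ha$home == 1L))
  expect_true(all(ha$events == "none"))
  expect_equal(average_cost(ha), 0)
})

test_that("a node in a different always-present community each step costs T-1", {
  # six communities kept present by six resident nodes; the wanderer visits
  # a different one at each of 6 time steps -> minimal cost 5 (unit costs)
  m <- matrix(1:6, nrow = 1, dimnames = list("wander", NULL))
  residents <- matrix(1:6, nrow = 6, ncol = 6,
                      dimnames = list(paste0("r", 1:6), NULL))
  memb <- rbind(m, residents)
  ha <- assign_home(mk_tl(memb))
  expect_equal(unname(ha$node_cost["wander"]), 5)
  # oracle agreement on the same instance
  tl <- mk_tl(memb)
  cpres <- tempcomm:::.community_presence(tl)
  expect_equal(unname(ha$node_cost["wander"]),
               enumerate_node_cost(memb["wander", ], cpres))
})

test_that("a brief excursion is a visit, not two switches", {
  # home A throughout with one visit (cost 1) beats switching out and back
  memb <- rbind(x = c(1L, 1L, 2L, 1L),
                a2 = c(1L, 1L, 1L, 1L),
                b = c(2L, 2L, 2L, 2L))
  ha <- assign_home(mk_tl(memb))
  expect_equal(unname(ha$node_cost["x"]), 1)
  expect_equal(unname(ha$home["x", ]), rep(1L, 4))
  expect_equal(unname(ha$events["x", 3]), "visit")
})

test_that("absence costs apply only while the home community is present", {
  # node absent at t=2 and t=3; its community vanishes at t=3 only
  memb <- rbind(x = c(1L, NA, NA, 1L),
                y = c(1L, 1L, NA, 1L),
                z = c(2L, 2L, 2L, 2L))
  ha <- assign_home(mk_tl(memb))
  expect_equal(unname(ha$events["x", 2]), "absence")
  expect_equal(unname(ha$events["x", 3]), "exempt-absence")
  expect_equal(unname(ha$node_cost["x"]), 1)
  # community 1 present at t = 1, 2, 4 (y keeps it alive at t=2)
  tl <- mk_tl(memb)
  expect_true(community_present(tl, 1, 2))
  expect_false(community_present(tl, 1, 3))
})

test_that("a node never observed in any group is an error", {
  memb <- rbind(x = c(1L, 1L), y = c(NA_integer_, NA_integer_))
  expect_error(assign_home(mk_tl(memb)), "'y'")
})

test_that("DP equals exhaustive enumeration on random instances", {
  set.seed(53)
  for (rep in 1:60) {
    TT <- sample(2:6, 1)
    K <- sample(2:5, 1)
    n <- sample(3:6, 1)
    memb <- matrix(sample(c(seq_len(K), NA), n * TT, replace = TRUE,
                          prob = c(rep(1, K), 0.35)),
                   nrow = n, dimnames = list(sprintf("v%02d", 1:n), NULL))
    # every community id must occur somewhere; every node somewhere
    memb[1, ] <- rep_len(seq_len(K), TT)
    for (i in seq_len(n)) if (all(is.na(memb[i, ])))
      memb[i, sample(TT, 1)] <- sample(K, 1)
    tl <- mk_tl(memb)
    costs <- runif(3, 0.2, 2)
    ha <- assign_home(tl, switch_cost = costs[1], visit_cost = costs[2],
                      absence_cost = costs[3])
    cpres <- tempcomm:::.community_presence(tl)
    for (i in seq_len(n)) {
      expect_equal(unname(ha$node_cost[i]),
                   enumerate_node_cost(memb[i, ], cpres, costs[1], costs[2],
                                       costs[3]),
                   tolerance = 1e-10)
    }
    # total cost is the sum of itemised event costs
    ev <- unlist(strsplit(as.vector(ha$events), "+", fixed = TRUE))
    expect_equal(ha$total_cost,
                 sum(ev == "switch") * costs[1] +
                   sum(ev == "visit") * costs[2] +
                   sum(ev == "absence") * costs[3],
                 tolerance = 1e-10)
  }
})

test_that("restricting homes to observed communities loses nothing", {
  set.seed(59)
  for (rep in 1:20) {
    TT <- sample(2:5, 1)
    K <- 4
    memb <- matrix(sample(c(1:4, NA), 4 * TT, replace = TRUE),
                   nrow = 4, dimnames = list(paste0("v", 1:4), NULL))
    memb[1, ] <- rep_len(1:4, TT)
    for (i in 1:4) if (all(is.na(memb[i, ])))
      memb[i, sample(TT, 1)] <- sample(4, 1)
    tl <- mk_tl(memb)
    ha <- assign_home(tl)
    cpres <- tempcomm:::.community_presence(tl)
    for (i in 1:4) {
      all_comm <- sort(unique(memb[!is.na(memb)]))
      expect_equal(unname(ha$node_cost[i]),
                   enumerate_node_cost(memb[i, ], cpres,
                                       candidates = all_comm),
                   tolerance = 1e-10)
    }
  }
})

test_that("cost scaling and absence decoupling behave as invariants say", {
  memb <- rbind(x = c(1L, 2L, NA, 1L), y = c(1L, 1L, 1L, 1L),
                z = c(2L, 2L, 2L, 2L))
  tl <- mk_tl(memb)
  base <- assign_home(tl)
  lam <- 2.5
  scaled <- assign_home(tl, switch_cost = lam, visit_cost = lam,
                        absence_cost = lam)
  expect_equal(scaled$node_cost, base$node_cost * lam)
  expect_identical(scaled$home, base$home)
  # with absence_cost = 0 the cost depends only on the membership entries
  memb2 <- memb
  memb2["x", 3] <- NA  # already NA; flip y's presence instead
  memb2["y", 3] <- NA
  a1 <- assign_home(mk_tl(memb), absence_cost = 0)
  a2 <- assign_home(mk_tl(memb2), absence_cost = 0)
  expect_equal(unname(a1$node_cost["x"]), unname(a2$node_cost["x"]))
})

test_that("average cost is C/(N*T)", {
  expect_equal(round(average_cost(total_cost = 37, n_nodes = 18,
                                  n_times = 14), 3), 0.147)
  expect_equal(average_cost(total_cost = 12, n_nodes = 4, n_times = 6), 0.5)
  m <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(average_cost(assign_home(mk_tl(m))), 0)
})
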