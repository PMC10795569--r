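std_intercepts <- intercepts_from_thresholds(c(-1, 0, 1), 1.5)

test_that("nominal-model category probabilities match hand evaluation", {
  p <- mnrm_category_probs(c(0, 0), c(1.5, 1.5), std_intercepts, scoring_matrix(4))
  expect_equal(p, exp(c(0, 1.5, 1.5, 0)) / sum(exp(c(0, 1.5, 1.5, 0))))
  expect_equal(round(p, 4), c(0.0912, 0.4088, 0.4088, 0.0912))
  # at ERS = 1 all four linear predictors equal 1.5: uniform
  expect_equal(
    mnrm_category_probs(c(0, 1), c(1.5, 1.5), std_intercepts, scoring_matrix(4)),
    rep(0.25, 4)
  )
  expect_equal(
    mnrm_category_probs(c(2, -1), c(0, 0), rep(0, 4), scoring_matrix(4)),
    rep(0.25, 4)
  )
  expect_error(
    mnrm_category_probs(c(0, 0, 0), c(1.5, 1.5), std_intercepts, scoring_matrix(4)),
    "dimensions"
  )
  expect_error(
    mnrm_category_probs(c(NA, 0), c(1.5, 1.5), std_intercepts, scoring_matrix(4)),
    "finite"
  )
})

test_that("the GPCM is the nominal model without the ERS dimension", {
  expect_identical(
    gpcm_category_probs(0, 1.5, std_intercepts),
    mnrm_category_probs(c(0, 5), c(1.5, 0), std_intercepts, scoring_matrix(4))
  )
  expect_equal(round(gpcm_category_probs(0, 1.5, std_intercepts), 4),
               c(0.0912, 0.4088, 0.4088, 0.0912))
  # monotone limit: all mass ends in the top category
  expect_gt(gpcm_category_probs(12, 1.5, std_intercepts)[4], 0.999)
})

test_that("probabilities are simplex vectors everywhere", {
  set.seed(31)
  tree <- tibble::tibble(item = 1L, a1 = 2, d1 = -0.4, a_sub = 1.4,
                         a_ers = 1.1, d2 = 0.3, d3 = -0.7)
  for (i in 1:50) {
    th <- rnorm(2, sd = 2)
    p1 <- mnrm_category_probs(th, runif(2, 0.1, 3), rnorm(4), scoring_matrix(4))
    p2 <- irtree_category_probs(th, tree)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(sum(p2), 1, tolerance = 1e-12)
    expect_true(all(p1 > 0) && all(p2 > 0))
  }
})

test_that("IRTree node probabilities respect the constraint structure", {
  flat <- tibble::tibble(item = 1L, a1 = 1.5, d1 = 0, a_sub = 1.2,
                         a_ers = 0.9, d2 = 0, d3 = 0)
  expect_equal(unname(irtree_node_probs(c(0, 0), flat)), rep(0.5, 3))
  expect_equal(irtree_node_probs(c(1, 0), flat)[["node1"]],
               1 / (1 + exp(-1.5)), tolerance = 1e-12)
  # ERS pushes extremity up on the agreement side, down on disagreement
  lo <- irtree_node_probs(c(0.3, -1), flat)
  hi <- irtree_node_probs(c(0.3, 1), flat)
  expect_lt(hi[["node2"]], lo[["node2"]])
  expect_gt(hi[["node3"]], lo[["node3"]])
  # node 1 never depends on ERS
  expect_equal(lo[["node1"]], hi[["node1"]])
})

test_that("IRTree category probabilities are branch products", {
  tree <- tibble::tibble(item = 1L, a1 = 2.2, d1 = -1.1, a_sub = 1.7,
                         a_ers = 1.4, d2 = 0.8, d3 = -2.4)
  set.seed(14)
  for (i in 1:25) {
    th <- rnorm(2, sd = 1.5)
    pn <- irtree_node_probs(th, tree)
    pc <- irtree_category_probs(th, tree)
    expect_equal(pc[1], (1 - pn[["node1"]]) * (1 - pn[["node2"]]))
    expect_equal(pc[2], (1 - pn[["node1"]]) * pn[["node2"]])
    expect_equal(pc[3], pn[["node1"]] * (1 - pn[["node3"]]))
    expect_equal(pc[4], pn[["node1"]] * pn[["node3"]])
    # marginalization identity: agreement probability equals the node-1 curve
    expect_equal(pc[3] + pc[4], pn[["node1"]], tolerance = 1e-15)
  }
})

test_that("pseudo-item expansion reproduces the observed-response mapping", {
  tab <- pseudo_items(1:4)
  expect_identical(tab$node1, c(0L, 0L, 1L, 1L))
  expect_identical(tab$node2, c(0L, 1L, NA, NA))
  expect_identical(tab$node3, c(NA, NA, 0L, 1L))
  # exactly one of node2/node3 missing, tied to node1's branch
  expect_identical(is.na(tab$node2), tab$node1 == 1L)
  expect_identical(is.na(tab$node3), tab$node1 == 0L)
  expect_identical(pseudo_items(c(4L, 2L))$node3, c(1L, NA))
  expect_error(pseudo_items(5), "1..4")
  expect_error(pseudo_items(0:2), "1..4")
})

test_that("agreement is ERS-invariant under the IRTree, conditional extremeness under the MNRM", {
  th2 <- seq(-3, 3, length.out = 41)
  tree <- tree_item_fixture <- tibble::tibble(
    item = 1L, a1 = 2.1, d1 = 0.6, a_sub = 1.6, a_ers = 1.3, d2 = 0.5, d3 = -1.9
  )
  item <- std_item()
  for (t1 in c(-2, 0, 1)) {
    grid <- cbind(t1, th2)
    agree_tree <- agreement_prob("irtree", grid, tree)
    expect_lt(diff(range(agree_tree)), 1e-10)
    cond_mnrm <- conditional_extreme_agreement("mnrm", grid, item)
    expect_lt(diff(range(cond_mnrm)), 1e-10)
    # and the off-diagonal properties genuinely vary (the models differ)
    if (t1 != 0) {
      expect_gt(diff(range(agreement_prob("mnrm", grid, item))), 0.01)
    }
    expect_gt(diff(range(conditional_extreme_agreement("irtree", grid, tree))), 0.003)
  }
  # symmetric item at theta1 = 0: agreement exactly 1/2 for every ERS value
  expect_equal(agreement_prob("mnrm", cbind(0, th2), item), rep(0.5, 41))
  # and both families give a 50:50 extreme split at the symmetric point
  expect_equal(conditional_extreme_agreement("mnrm", cbind(0, 0), item), 0.5)
})

test_that("adding a constant to all nominal intercepts changes nothing", {
  set.seed(8)
  for (i in 1:10) {
    th <- rnorm(2)
    ci <- rnorm(4)
    expect_equal(
      mnrm_category_probs(th, c(1.5, 1.5), ci, scoring_matrix(4)),
      mnrm_category_probs(th, c(1.5, 1.5), ci + 3.7, scoring_matrix(4))
    )
  }
})
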