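test_that("person sampling matches the two-group trait model", {
  p <- sample_persons(100000, delta_ers = 1, seed = 123)
  g2 <- p[p$group == 2, ]
  g1 <- p[p$group == 1, ]
  se <- 1 / sqrt(nrow(g2))
  expect_lt(abs(mean(g2$theta_ers) - 1), 3 * se)
  expect_lt(abs(mean(g1$theta_ers)), 3 * se)
  expect_lt(abs(mean(p$theta_sub)), 3 / sqrt(nrow(p)))
  expect_lt(abs(stats::cor(p$theta_sub, p$theta_ers)), 3 / sqrt(nrow(p)))
  # determinism
  expect_identical(p, sample_persons(100000, delta_ers = 1, seed = 123))
  expect_error(sample_persons(0), "positive")
})

test_that("simulated category frequencies match the probability kernels", {
  # all persons at theta = (0, 0): frequencies must match the softmax of
  # the symmetric item, (0.0912, 0.4088, 0.4088, 0.0912)
  n <- 100000
  persons <- tibble::tibble(person = seq_len(n), group = rep(1:2, each = n / 2),
                            theta_sub = 0, theta_ers = 0)
  item <- std_item()
  p <- mnrm_category_probs(c(0, 0), c(1.5, 1.5),
                           as.numeric(item[, c("c1", "c2", "c3", "c4")]),
                           scoring_matrix(4))
  # aggregate over independent streams: a systematic sampler error grows
  # with the total count while single-stream flukes wash out
  tot <- numeric(4)
  for (seed in 1:4) {
    dat <- simulate_responses(persons, item, "mnrm", seed = seed)
    tot <- tot + tabulate(dat$y_1, 4)
  }
  freq <- tot / sum(tot)
  se <- sqrt(p * (1 - p) / sum(tot))
  expect_true(all(abs(freq - p) < 4 * se))
  expect_gt(stats::chisq.test(tot, p = p)$p.value, 1e-4)
})

test_that("the two IRTree simulation paths agree in distribution", {
  tree <- tibble::tibble(item = 1L, a1 = 2.2, d1 = -1.1, a_sub = 1.7,
                         a_ers = 1.4, d2 = 0.8, d3 = -2.4)
  n <- 200000
  persons <- tibble::tibble(person = seq_len(n), group = rep(1:2, each = n / 2),
                            theta_sub = 0.4, theta_ers = -0.3)
  # path 1: sequential node Bernoullis (the simulator)
  seq_dat <- simulate_responses(persons, tree, "irtree", seed = 6)
  obs <- tabulate(seq_dat$y_1, 4)
  # path 2: the closed-form category probabilities
  p <- irtree_category_probs(c(0.4, -0.3), tree)
  chi <- stats::chisq.test(obs, p = p)
  expect_gt(chi$p.value, 1e-4)
})

test_that("the control generator ignores the ERS trait entirely", {
  persons <- sample_persons(20000, delta_ers = 0, seed = 11)
  dat <- simulate_responses(persons, sym_items(2), "gpcm", seed = 12,
                            keep_traits = TRUE)
  extreme <- as.integer(dat$y_1 %in% c(1L, 4L))
  fitl <- stats::glm(extreme ~ dat$theta_ers, family = stats::binomial())
  z <- summary(fitl)$coefficients[2, 3]
  expect_lt(abs(z), 3.5)
  # whereas the MNRM generator does use it
  dat2 <- simulate_responses(persons, sym_items(2), "mnrm", seed = 12,
                             keep_traits = TRUE)
  extreme2 <- as.integer(dat2$y_1 %in% c(1L, 4L))
  z2 <- summary(stats::glm(extreme2 ~ dat2$theta_ers,
                           family = stats::binomial()))$coefficients[2, 3]
  expect_gt(z2, 10)
})

test_that("generation is byte-reproducible from its seeds", {
  persons <- sample_persons(50, delta_ers = -1, seed = 3)
  a <- simulate_responses(persons, sym_items(4), "mnrm", seed = 4)
  b <- simulate_responses(persons, sym_items(4), "mnrm", seed = 4)
  expect_identical(a, b)
})

test_that("derived IRTree items mimic the symmetric nominal generator", {
  items <- sym_items(10)
  tree <- tree_truth(c(-1, 0, 1))
  expect_true(attr(tree, "fit")$converged)
  # sign convention: every ERS slope positive after reflection handling
  expect_true(all(tree$a_ers > 0))
  # category-probability surfaces track the generating MNRM's over the
  # trait region where most persons live; the families genuinely
  # separate as |ERS| grows (that residual mismatch is the phenomenon
  # under study), so closeness is tightest at the prior mode
  g <- as.matrix(expand.grid(t1 = -2:2, t2 = -2:2))
  dmax <- 0
  for (j in 1:10) {
    pm <- ersirt:::prob_matrix("mnrm", items, j, g)
    pt <- ersirt:::prob_matrix("irtree", tree, j, g)
    dmax <- max(dmax, max(abs(pm - pt)))
    d0 <- max(abs(
      mnrm_category_probs(c(0, 0), c(items$a_sub[j], items$a_ers[j]),
                          as.numeric(items[j, c("c1", "c2", "c3", "c4")]),
                          scoring_matrix(4)) -
        irtree_category_probs(c(0, 0), tree[j, ])
    ))
    expect_lt(d0, 0.05)
  }
  expect_lt(dmax, 0.15)
})
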