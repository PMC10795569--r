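test_that("degenerate one-node quadrature gives the kernel probability exactly", {
  item <- std_item()
  dat <- tibble::tibble(person = 1L, group = 1L, y_1 = 3L)
  ll <- marginal_loglik(dat, item, "mnrm", nq = 1)
  p <- mnrm_category_probs(c(0, 0), c(1.5, 1.5),
                           as.numeric(item[, c("c1", "c2", "c3", "c4")]),
                           scoring_matrix(4))
  expect_equal(ll, log(p[3]), tolerance = 1e-12)
})

test_that("quadrature likelihood matches brute-force Monte-Carlo integration", {
  items <- sym_items(3)
  persons <- sample_persons(3, delta_ers = 0, seed = 3)
  dat <- simulate_responses(persons, items, "mnrm", seed = 4)
  Y <- as.matrix(dat[, c("y_1", "y_2", "y_3")])
  set.seed(7)
  M <- 200000
  th <- cbind(rnorm(M), rnorm(M))
  ll_mc <- 0
  se2 <- 0
  for (i in seq_len(nrow(Y))) {
    L <- rep(1, M)
    for (j in 1:3) {
      pj <- ersirt:::prob_matrix("mnrm", items, j, th)
      L <- L * pj[, Y[i, j]]
    }
    ll_mc <- ll_mc + log(mean(L))
    se2 <- se2 + stats::var(L) / (M * mean(L)^2)  # delta-method on log
  }
  ll_q <- marginal_loglik(dat, items, "mnrm")
  expect_lt(abs(ll_q - ll_mc), 3 * sqrt(se2))
})

test_that("log-likelihood is additive over duplicated persons", {
  items <- sym_items(4)
  dat <- small_mnrm_data(30, items = items)
  dat2 <- dplyr::bind_rows(dat, dat)
  dat2$person <- seq_len(nrow(dat2))
  expect_equal(
    2 * marginal_loglik(dat, items, "mnrm"),
    marginal_loglik(dat2, items, "mnrm"),
    tolerance = 1e-10
  )
})

test_that("information criteria follow their closed forms", {
  ix <- fit_indices(-100, 5, 100)
  expect_equal(ix$AIC, 210)
  expect_equal(ix$BIC, 200 + 5 * log(100))
  expect_equal(round(ix$BIC, 3), 223.026)
  expect_equal(ix$SABIC, 200 + 5 * log(102 / 24))
  expect_equal(ix$HQ, 200 + 10 * log(log(100)))
  expect_error(fit_indices(-100, 5, 1), "exceed")
  expect_error(fit_indices(-100, 0, 50), "positive")
})

test_that("plain EM never decreases its objective", {
  dat <- small_mnrm_data(250)
  for (model in c("gpcm", "mnrm", "irtree")) {
    f <- fit_ers(dat, model, accelerate = FALSE, max_iter = 200)
    # ll_trace records the maximized objective (log-likelihood plus the
    # ERS-slope stabilizing prior); on the fixed quadrature grid the EM
    # guarantee holds exactly
    expect_true(all(diff(f$ll_trace) > -1e-8),
                label = paste(model, "monotone"))
  }
})

test_that("the accelerated fit reaches the same solution as plain EM", {
  dat <- small_mnrm_data(250)
  fa <- fit_ers(dat, "gpcm")
  fp <- fit_ers(dat, "gpcm", accelerate = FALSE)
  expect_lt(abs(fa$loglik - fp$loglik), 1e-3)
  expect_equal(fa$focal$var_sub, fp$focal$var_sub, tolerance = 1e-2)
})

test_that("the maximized likelihood beats the generating parameters", {
  items <- sym_items(5)
  dat <- small_mnrm_data(400, items = items, seed = 17)
  f <- fit_ers(dat, "mnrm")
  fc <- matrix(c(f$focal$var_sub, f$focal$cov_sub_ers,
                 f$focal$cov_sub_ers, f$focal$var_ers), 2)
  ll_est <- marginal_loglik(dat, f$items, "mnrm",
                            focal_mean = c(f$focal$mean_sub, f$focal$mean_ers),
                            focal_cov = fc)
  ll_true <- marginal_loglik(dat, items, "mnrm",
                             focal_mean = c(0, 1), focal_cov = diag(2))
  expect_gte(ll_est, ll_true - 1e-6)
})

test_that("each family recovers its own generating parameters", {
  # moderate replication of the self-consistency (zero-diagonal) design:
  # n = 2000 per group, a few replications, slopes within 0.15 and focal
  # group parameters within 0.05 of truth on average
  n_reps <- 4
  items <- sym_items(10)
  tree <- tree_truth(c(-1, 0, 1))
  for (family in c("gpcm", "mnrm", "irtree")) {
    gen_items <- if (family == "irtree") tree else items
    est <- purrr::map_dfr(seq_len(n_reps), function(r) {
      persons <- sample_persons(2000, delta_ers = if (family == "gpcm") 0 else 1,
                                seed = 7000 + r)
      dat <- simulate_responses(persons, gen_items, family, seed = 7100 + r)
      f <- fit_ers(dat, family)
      tibble::tibble(
        mu = f$focal$mean_sub, v = f$focal$var_sub,
        mu_ers = f$focal$mean_ers,
        slopes = list(f$items$a_sub)
      )
    })
    # average slope estimate per item within 0.15 of its generating value
    slope_means <- colMeans(do.call(rbind, est$slopes))
    expect_lt(max(abs(slope_means - gen_items$a_sub)), 0.15)
    expect_lt(abs(mean(est$mu)), 0.05)
    expect_lt(abs(mean(est$v) - 1), 0.05 + 2 * stats::sd(est$v) / sqrt(n_reps))
    if (family != "gpcm") {
      expect_lt(abs(mean(est$mu_ers) - 1), 0.05 + 2 * stats::sd(est$mu_ers) / sqrt(n_reps))
    }
  }
})

test_that("EAP scores behave like posterior means", {
  items <- sym_items(5)
  dat <- small_mnrm_data(200, seed = 55, items = items)
  f <- fit_ers(dat, "gpcm")
  sc <- eap_scores(f, dat)
  expect_identical(nrow(sc), nrow(dat))
  # equal slopes make the total score sufficient: within a group the
  # substantive EAP is monotone in the sum, and an all-4s pattern
  # outranks every observed pattern
  g1 <- which(dat$group == 1)
  sums <- rowSums(dat[g1, paste0("y_", 1:5)])
  expect_gte(stats::cor(sc$eap_sub[g1], sums, method = "spearman"), 0.98)
  all4 <- dat[1, ]
  all4[, paste0("y_", 1:5)] <- 4L
  sc4 <- eap_scores(f, all4)
  expect_gte(sc4$eap_sub, max(sc$eap_sub[g1]) - 1e-10)
  # degenerate one-node quadrature collapses to the node location
  f1 <- fit_ers(dat, "gpcm", nq = 1, max_iter = 5)
  sc1 <- eap_scores(f1, dat[dat$group == 1, ])
  expect_true(all(abs(sc1$eap_sub) < 1e-12))
})

test_that("EAP substantive scores track the true traits", {
  items <- sym_items(20)
  persons <- sample_persons(1000, delta_ers = 1, seed = 66)
  dat <- simulate_responses(persons, items, "mnrm", seed = 67)
  f <- fit_ers(dat, "mnrm")
  sc <- eap_scores(f, dat)
  expect_gt(stats::cor(sc$eap_sub, persons$theta_sub), 0.7)
  expect_gt(stats::cor(sc$eap_ers, persons$theta_ers), 0.5)
})

test_that("model comparison reports nesting and index winners coherently", {
  dat <- small_mnrm_data(400, seed = 31)
  fits <- list(
    gpcm = fit_ers(dat, "gpcm"),
    mnrm = fit_ers(dat, "mnrm")
  )
  # the GPCM is nested in the MNRM: its likelihood cannot win
  expect_gte(fits$mnrm$loglik, fits$gpcm$loglik)
  tab <- select_model(fits)
  expect_identical(nrow(tab), 2L)
  expect_true(tab$best_AIC[tab$model == "mnrm"])
  # identical fits tie on every index
  tab2 <- select_model(list(a = fits$gpcm, b = fits$gpcm))
  expect_true(all(tab2$best_BIC))
  # refusing to compare fits of different data
  other <- small_mnrm_data(120, seed = 77)
  f_other <- fit_ers(other, "gpcm")
  expect_error(select_model(list(fits$gpcm, f_other)), "same data")
})

test_that("items with unobserved categories are dropped with a warning", {
  dat <- small_mnrm_data(150, seed = 41, items = sym_items(4))
  dat$y_1[dat$y_1 == 4L] <- 3L   # kill category 4 of item 1
  expect_warning(f <- fit_ers(dat, "gpcm"), "unobserved")
  expect_identical(f$n_items, 3L)
})
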