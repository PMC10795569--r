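# Synthetic-data generators: item sets, person traits, and categorical
# responses under each model family, plus the large-sample derivation of
# "true" IRTree item parameters from a nominal-model generator.

#' Build a nominal-model item set with shifted thresholds
#'
#' All items share the same slopes on both dimensions; item `j`'s
#' thresholds are the base set plus a location shift `m_j`, with the
#' `m_j` equally spaced between -0.5 and 0.5 so that item difficulty
#' varies across the scale as in a real questionnaire.
#'
#' @param base_thresholds Numeric vector of 3 base thresholds, e.g.
#'   `c(-1, 0, 1)` (symmetric) or `c(0, 1, 2)` (asymmetric).
#' @param slope Common slope for the substantive and ERS dimensions
#'   (default 1.5).
#' @param n_items Number of items (at least 2).
#' @param shift_range Endpoints of the equally spaced shifts.
#' @return A tibble with columns `item, a_sub, a_ers, c1..c4`.
#' @examples
#' make_item_set(c(-1, 0, 1), n_items = 10)
#' @export
make_item_set <- function(base_thresholds, slope = 1.5, n_items = 10,
                          shift_range = c(-0.5, 0.5)) {
  n_items <- as.integer(n_items)
  if (is.na(n_items) || n_items < 2L) abort("`n_items` must be >= 2.")
  if (length(base_thresholds) != 3L) {
    abort("`base_thresholds` must have length 3 (four categories).")
  }
  m <- seq(shift_range[1L], shift_range[2L], length.out = n_items)
  cmat <- t(vapply(
    m,
    function(mj) intercepts_from_thresholds(base_thresholds + mj, slope),
    numeric(4L)
  ))
  tibble::tibble(
    item = seq_len(n_items),
    a_sub = slope, a_ers = slope,
    c1 = cmat[, 1L], c2 = cmat[, 2L], c3 = cmat[, 3L], c4 = cmat[, 4L]
  )
}

#' Draw person traits for a two-group design
#'
#' Group 1 (reference) traits are iid standard bivariate normal with
#' zero correlation; group 2 (focal) has the same substantive
#' distribution but its ERS trait mean shifted by `delta_ers`.  The two
#' traits are independent at generation.
#'
#' @param n_per_group Persons per group.
#' @param delta_ers Focal-group ERS mean (reference mean is 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `person, group, theta_sub, theta_ers`.
#' @export
sample_persons <- function(n_per_group, delta_ers = 0, seed = NULL) {
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 1L) {
    abort("`n_per_group` must be a positive integer.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_group
  tibble::tibble(
    person = seq_len(n),
    group = rep(1:2, each = n_per_group),
    theta_sub = rnorm(n),
    theta_ers = rnorm(n, mean = rep(c(0, delta_ers), each = n_per_group))
  )
}

#' Simulate categorical responses under a model family
#'
#' Each response is drawn from the family's category distribution at the
#' person's latent traits.  The `"gpcm"` control family uses the nominal
#' kernel with the ERS dimension nulled, i.e. response style plays no
#' role in the generated data.  The `"irtree"` family draws the
#' sequential node Bernoullis directly (equivalent in distribution to
#' sampling from the category probabilities).
#'
#' @param persons Person tibble from [sample_persons()].
#' @param items Item table matching the family ([make_item_set()] for
#'   `"mnrm"`/`"gpcm"`, [derive_irtree_truth()] for `"irtree"`).
#' @param family `"mnrm"`, `"gpcm"` or `"irtree"`.
#' @param seed Optional integer seed.
#' @param keep_traits Keep the true trait columns in the result?
#' @return A wide response tibble: `person, group, y_1..y_J` (and the
#'   trait columns when `keep_traits = TRUE`).
#' @export
simulate_responses <- function(persons, items, family = c("mnrm", "gpcm", "irtree"),
                               seed = NULL, keep_traits = FALSE) {
  family <- match.arg(family)
  if (family == "irtree") check_tree_items(items) else check_mnrm_items(items)
  if (!is.null(seed)) set.seed(seed)
  theta <- cbind(persons$theta_sub, persons$theta_ers)
  n <- nrow(theta)
  J <- nrow(items)
  y <- matrix(NA_integer_, n, J)
  if (family == "irtree") {
    for (j in seq_len(J)) {
      it <- items[j, ]
      b1 <- runif(n) < plogis(it$a1 * theta[, 1L] + it$d1)
      b2 <- runif(n) < plogis(it$a_sub * theta[, 1L] - it$a_ers * theta[, 2L] + it$d2)
      b3 <- runif(n) < plogis(it$a_sub * theta[, 1L] + it$a_ers * theta[, 2L] + it$d3)
      y[, j] <- ifelse(b1, 3L + b3, 1L + b2)
    }
  } else {
    for (j in seq_len(J)) {
      p <- prob_matrix(family, items, j, theta)
      u <- runif(n)
      cp <- p[, 1L]
      yj <- rep(1L, n)
      for (k in 2:4) {
        yj[u > cp] <- k
        if (k < 4L) cp <- cp + p[, k]
      }
      y[, j] <- yj
    }
  }
  colnames(y) <- paste0("y_", seq_len(J))
  out <- dplyr::bind_cols(
    tibble::tibble(person = persons$person, group = persons$group),
    tibble::as_tibble(y)
  )
  if (keep_traits) {
    out$theta_sub <- persons$theta_sub
    out$theta_ers <- persons$theta_ers
  }
  out
}

#' Derive IRTree item parameters that mimic a nominal-model generator
#'
#' Simulates a large two-group sample from the nominal model and fits
#' the constrained IRTree to it; the resulting item estimates serve as
#' "true" IRTree generating values whose category-probability surfaces
#' are as close as possible to the nominal generator's, making the two
#' generating families maximally comparable.
#'
#' @param items Nominal-model item table.
#' @param n_per_group Persons per group for the derivation sample
#'   (default 500000; estimates are stable to about two decimals).
#' @param delta_ers Focal-group ERS mean used in the derivation sample.
#' @param seed Integer seed for the derivation sample.
#' @param nq Quadrature nodes per dimension for the IRTree fit.
#' @return An IRTree item tibble (`item, a1, d1, a_sub, a_ers, d2, d3`)
#'   with the fit stored in attribute `"fit"`.
#' @export
derive_irtree_truth <- function(items, n_per_group = 500000, delta_ers = 0,
                                seed = 1L, nq = NULL) {
  check_mnrm_items(items)
  persons <- sample_persons(n_per_group, delta_ers = delta_ers, seed = seed)
  dat <- simulate_responses(persons, items, "mnrm", seed = seed + 1L)
  fit <- fit_ers(dat, model = "irtree", nq = nq)
  if (!fit$converged) {
    warn("IRTree truth derivation did not meet the convergence tolerance; inspect attr(result, 'fit').")
  }
  out <- fit$items
  attr(out, "fit") <- fit
  out
}
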