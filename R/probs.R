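#' Category probabilities under the multidimensional nominal response model
#'
#' Divide-by-total (softmax) model: the probability of category `k` is
#' proportional to `exp(sum_v a_v * s_kv * theta_v + c_k)`, where the
#' fixed scoring matrix `s` assigns each category an integer score on
#' each latent dimension.
#'
#' @param theta Numeric vector of latent traits, one per scoring-matrix
#'   column (substantive first, ERS second).
#' @param slopes Positive slopes, one per dimension.
#' @param intercepts `K` category intercepts (first conventionally 0).
#' @param scoring `K x D` scoring matrix from [scoring_matrix()].
#' @return Length-`K` probability vector summing to 1.
#' @examples
#' mnrm_category_probs(
#'   c(0, 0), c(1.5, 1.5),
#'   intercepts_from_thresholds(c(-1, 0, 1), 1.5),
#'   scoring_matrix(4)
#' )
#' @export
mnrm_category_probs <- function(theta, slopes, intercepts, scoring) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    abort("`theta` must be finite numeric.")
  }
  d <- ncol(scoring)
  if (length(theta) != d || length(slopes) != d) {
    abort("dimensions of `theta`, `slopes` and `scoring` disagree.")
  }
  if (nrow(scoring) != length(intercepts)) {
    abort("`intercepts` length must match the scoring-matrix rows.")
  }
  eta <- drop(scoring %*% (slopes * theta)) + intercepts
  p <- exp(eta - max(eta))
  p / sum(p)
}

#' Category probabilities under the generalized partial credit model
#'
#' The response-style-free control: the nominal model restricted to the
#' single substantive dimension with the ordinal scoring `0..K-1`.
#'
#' @param theta1 Substantive trait value.
#' @param slope Positive item slope.
#' @param intercepts `K` category intercepts.
#' @return Length-`K` probability vector.
#' @export
gpcm_category_probs <- function(theta1, slope, intercepts) {
  mnrm_category_probs(
    theta1, slope, intercepts,
    scoring_matrix(length(intercepts), ers = FALSE)
  )
}

#' Node endorsement probabilities of the three-node IRTree
#'
#' The observed four-category response is decomposed into sequential
#' binary pseudo-items: node 1 (agreement) is a two-parameter logistic
#' item in the substantive trait alone; nodes 2 and 3 (extremity given
#' disagreement / agreement) load on both traits, with a common
#' substantive slope and an ERS slope entering node 2 with a minus sign
#' and node 3 with a plus sign.
#'
#' @param theta Length-2 numeric `(theta_sub, theta_ers)`.
#' @param item One row of an IRTree item table (columns `a1, d1, a_sub,
#'   a_ers, d2, d3`), or a named list with those elements.
#' @return Named length-3 vector of `P(node = 1)` for nodes 1..3.
#' @export
irtree_node_probs <- function(theta, item) {
  if (!is.numeric(theta) || length(theta) != 2L || any(!is.finite(theta))) {
    abort("`theta` must be 2 finite numbers.")
  }
  p1 <- plogis(item$a1 * theta[1L] + item$d1)
  p2 <- plogis(item$a_sub * theta[1L] - item$a_ers * theta[2L] + item$d2)
  p3 <- plogis(item$a_sub * theta[1L] + item$a_ers * theta[2L] + item$d3)
  c(node1 = p1, node2 = p2, node3 = p3)
}

#' Category probabilities under the three-node IRTree
#'
#' Products of the node Bernoullis along each branch: categories 1 and 2
#' require disagreement at node 1 and are split by node 2; categories 3
#' and 4 require agreement and are split by node 3.
#'
#' @inheritParams irtree_node_probs
#' @return Length-4 probability vector.
#' @export
irtree_category_probs <- function(theta, item) {
  p <- irtree_node_probs(theta, item)
  c(
    (1 - p[[1L]]) * (1 - p[[2L]]),
    (1 - p[[1L]]) * p[[2L]],
    p[[1L]] * (1 - p[[3L]]),
    p[[1L]] * p[[3L]]
  )
}

#' Pseudo-item expansion of observed four-category responses
#'
#' Maps each observed category to the three binary node outcomes, with
#' structural missingness (`NA`) on the branch not traversed: the
#' extremity-of-disagreement node is only observed for categories 1-2,
#' the extremity-of-agreement node only for categories 3-4.
#'
#' @param y Integer vector of observed categories in `1..4`.
#' @return A tibble with columns `y`, `node1`, `node2`, `node3`
#'   (integers 0/1 or `NA`), one row per element of `y`.
#' @examples
#' pseudo_items(1:4)
#' @export
pseudo_items <- function(y) {
  if (any(is.na(y)) || !all(y %in% 1:4)) {
    abort("`y` must contain categories 1..4 only.")
  }
  y <- as.integer(y)
  map <- matrix(
    c(
      0L, 0L, NA_integer_,
      0L, 1L, NA_integer_,
      1L, NA_integer_, 0L,
      1L, NA_integer_, 1L
    ),
    nrow = 4L, byrow = TRUE,
    dimnames = list(NULL, c("node1", "node2", "node3"))
  )
  tibble::as_tibble(map[y, , drop = FALSE]) |>
    tibble::add_column(y = y, .before = 1L)
}

# ---- vectorized kernels over a grid of trait values -----------------------
# These are the work-horses shared by the simulators and the estimator:
# category probabilities for every row of an n x D trait matrix, for one
# item, returned as an n x K matrix.

mnrm_prob_matrix <- function(theta, a_sub, a_ers, intercepts, scoring) {
  eta <- outer(theta[, 1L], scoring[, 1L] * a_sub)
  if (ncol(scoring) > 1L && ncol(theta) > 1L) {
    eta <- eta + outer(theta[, 2L], scoring[, 2L] * a_ers)
  }
  eta <- sweep(eta, 2L, intercepts, "+")
  m <- apply(eta, 1L, max)
  p <- exp(eta - m)
  p / rowSums(p)
}

irtree_prob_matrix <- function(theta, item) {
  p1 <- plogis(item$a1 * theta[, 1L] + item$d1)
  p2 <- plogis(item$a_sub * theta[, 1L] - item$a_ers * theta[, 2L] + item$d2)
  p3 <- plogis(item$a_sub * theta[, 1L] + item$a_ers * theta[, 2L] + item$d3)
  cbind(
    (1 - p1) * (1 - p2),
    (1 - p1) * p2,
    p1 * (1 - p3),
    p1 * p3
  )
}

# n x K probability matrix for item row `j` of an item table under a family
prob_matrix <- function(family, items, j, theta) {
  switch(family,
    mnrm = mnrm_prob_matrix(
      theta, items$a_sub[j], items$a_ers[j],
      as.numeric(item_intercepts(items)[j, ]), scoring_matrix(4L)
    ),
    gpcm = mnrm_prob_matrix(
      theta[, 1L, drop = FALSE], items$a_sub[j], 0,
      as.numeric(item_intercepts(items)[j, ]), scoring_matrix(4L, ers = FALSE)
    ),
    irtree = irtree_prob_matrix(theta, items[j, ]),
    abort(paste0("unknown model family: ", family))
  )
}

#' Probability of agreement with an item
#'
#' The probability of responding 3 or 4 of a four-category item, as a
#' function of the latent traits.  Under the IRTree this never depends
#' on ERS (the agreement node has no ERS loading); under the nominal
#' model it generally does, the more so the less symmetric the item
#' thresholds are around the respondent's substantive level.
#'
#' @param family `"mnrm"`, `"gpcm"` or `"irtree"`.
#' @param theta Numeric matrix (rows = trait vectors) or a single trait
#'   vector.
#' @param item One row of the matching item table.
#' @return Numeric vector of agreement probabilities, one per trait row.
#' @export
agreement_prob <- function(family, theta, item) {
  theta <- to_theta_matrix(theta)
  p <- prob_matrix(match.arg(family, c("mnrm", "gpcm", "irtree")),
                   item, 1L, theta)
  p[, 3L] + p[, 4L]
}

#' Probability of agreement given an extreme response
#'
#' `P(Y = 4 | Y in {1, 4})`.  Under the nominal model the ERS scores of
#' the two extreme categories are equal, so ERS cancels from the odds
#' and the curve is flat in ERS; under the IRTree it is not.
#'
#' @inheritParams agreement_prob
#' @return Numeric vector of conditional probabilities.
#' @export
conditional_extreme_agreement <- function(family, theta, item) {
  theta <- to_theta_matrix(theta)
  p <- prob_matrix(match.arg(family, c("mnrm", "gpcm", "irtree")),
                   item, 1L, theta)
  p[, 4L] / (p[, 1L] + p[, 4L])
}

to_theta_matrix <- function(theta) {
  if (is.matrix(theta)) theta else matrix(theta, nrow = 1L)
}
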