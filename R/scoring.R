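#' Scoring matrix linking item categories to latent dimensions
#'
#' Builds the fixed integer scoring matrix of the nominal response model.
#' Column 1 carries the ordinal substantive scores `0, 1, ..., K - 1`
#' (the partial-credit pattern); when `ers = TRUE` a second column flags
#' the two extreme categories with a 1, so that the second latent
#' dimension (extreme response style, ERS) pushes probability mass
#' symmetrically towards both scale endpoints.
#'
#' @param n_cat Number of response categories `K` (at least 2).
#' @param ers Include the ERS column?
#' @return An integer matrix with `n_cat` rows and 1 or 2 columns, with
#'   column names `"sub"` and (optionally) `"ers"`.
#' @examples
#' scoring_matrix(4)          # GPCM pattern
#' scoring_matrix(4, ers = TRUE)
#' @export
scoring_matrix <- function(n_cat = 4, ers = TRUE) {
  n_cat <- as.integer(n_cat)
  if (is.na(n_cat) || n_cat < 2L) abort("`n_cat` must be an integer >= 2.")
  s <- matrix(0:(n_cat - 1L), ncol = 1L, dimnames = list(NULL, "sub"))
  if (ers) {
    flag <- integer(n_cat)
    flag[c(1L, n_cat)] <- 1L
    s <- cbind(s, ers = flag)
  }
  s
}

#' Convert thresholds to category intercepts
#'
#' In the nominal-model parameterization the category intercepts `c_k`
#' (first fixed at 0) relate to the more interpretable thresholds
#' `tau_g = (c_g - c_{g+1}) / a`: the substantive-trait value where
#' adjacent categories are equally likely at zero ERS.
#'
#' @param tau Numeric vector of `K - 1` thresholds.
#' @param slope Positive substantive slope `a`.
#' @return Numeric vector of `K` intercepts with first element 0.
#' @examples
#' intercepts_from_thresholds(c(-1, 0, 1), 1.5)  # 0 1.5 1.5 0
#' @export
intercepts_from_thresholds <- function(tau, slope) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0) {
    abort("`slope` must be a single positive number.")
  }
  if (!is.numeric(tau) || length(tau) < 1L || any(!is.finite(tau))) {
    abort("`tau` must be a finite numeric vector.")
  }
  c(0, -slope * cumsum(tau))
}

#' Convert category intercepts back to thresholds
#'
#' Inverse of [intercepts_from_thresholds()]; round-trips to machine
#' precision.
#'
#' @param intercepts Numeric vector of `K` category intercepts.
#' @param slope Positive substantive slope.
#' @return Numeric vector of `K - 1` thresholds.
#' @export
thresholds_from_intercepts <- function(intercepts, slope) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0) {
    abort("`slope` must be a single positive number.")
  }
  if (length(intercepts) < 2L) abort("`intercepts` must have length >= 2.")
  -diff(intercepts) / slope
}

# ---- item tables ----------------------------------------------------------

# Columns expected of a nominal-model (MNRM / GPCM) item table.
mnrm_item_cols <- c("item", "a_sub", "a_ers", "c1", "c2", "c3", "c4")
# Columns expected of an IRTree item table.  a1/d1: agreement node;
# a_sub: substantive slope shared by the two extremity nodes; a_ers: ERS
# slope of the agreement-side node (mirrored with a minus sign on the
# disagreement-side node); d2/d3: extremity-node intercepts.
tree_item_cols <- c("item", "a1", "d1", "a_sub", "a_ers", "d2", "d3")

check_mnrm_items <- function(items, arg = "items") {
  miss <- setdiff(mnrm_item_cols, names(items))
  if (length(miss)) {
    abort(paste0("`", arg, "` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(items$a_sub <= 0)) abort("substantive slopes must be positive")
  invisible(items)
}

check_tree_items <- function(items, arg = "items") {
  miss <- setdiff(tree_item_cols, names(items))
  if (length(miss)) {
    abort(paste0("`", arg, "` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(items)
}

# intercept matrix (J x K) from an item table
item_intercepts <- function(items) {
  as.matrix(items[, c("c1", "c2", "c3", "c4")])
}

#' Thresholds of a nominal-model item table
#'
#' @param items Item table as produced by [make_item_set()].
#' @return A tibble with columns `item`, `tau1`, `tau2`, `tau3`.
#' @export
item_thresholds <- function(items) {
  check_mnrm_items(items)
  tau <- t(apply(item_intercepts(items), 1L, function(ci) -diff(ci))) /
    items$a_sub
  tibble::tibble(
    item = items$item,
    tau1 = tau[, 1L], tau2 = tau[, 2L], tau3 = tau[, 3L]
  )
}
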