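# The simulation-study pipeline: run replications of a data-generating
# condition under one or more estimators, summarise focal-group bias,
# and compute the probability-curve reports that contrast the families.

#' Describe one data-generating condition
#'
#' @param generator Data-generating family: `"mnrm"`, `"irtree"` or
#'   `"gpcm"` (the no-response-style control).
#' @param n_items Number of items (10 or 20 in the core design).
#' @param base_thresholds Base threshold set, `c(-1, 0, 1)` (symmetric)
#'   or `c(0, 1, 2)` (asymmetric).
#' @param delta_ers Focal-group ERS mean shift (-1, 0 or 1 in the core
#'   design; ignored by the `"gpcm"` generator which carries no ERS).
#' @param n_per_group Persons per group in each replication.
#' @param n_reps Number of replications.
#' @return A list of class `"ers_condition"`.
#' @export
condition_spec <- function(generator = c("mnrm", "irtree", "gpcm"),
                           n_items = 10, base_thresholds = c(-1, 0, 1),
                           delta_ers = 0, n_per_group = 1000, n_reps = 100) {
  generator <- match.arg(generator)
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  structure(
    list(
      generator = generator, n_items = as.integer(n_items),
      base_thresholds = base_thresholds, delta_ers = delta_ers,
      n_per_group = as.integer(n_per_group), n_reps = as.integer(n_reps)
    ),
    class = "ers_condition"
  )
}

base_label <- function(base_thresholds) {
  paste0("[", paste(base_thresholds, collapse = ","), "]")
}

# deterministic substream seeds below 2^31, derived from one root seed
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run all replications of one condition under several estimators
#'
#' For each replication a fresh two-group sample is generated from the
#' condition's family (persons and responses on separate random
#' substreams of the root seed) and every requested estimator is fit to
#' the identical data set.
#'
#' @param cond A [condition_spec()].
#' @param estimators Character vector of fitted families.
#' @param seed Root integer seed for the condition.
#' @param nq Quadrature nodes per dimension passed to [fit_ers()].
#' @param tree_items IRTree item table to generate from when
#'   `cond$generator == "irtree"`; if `NULL` it is derived by
#'   [derive_irtree_truth()] with `truth_n` persons per group.
#' @param truth_n Derivation sample size per group for the IRTree truth.
#' @param ... Further arguments passed to [fit_ers()].
#' @return A tibble with one row per replication x estimator: condition
#'   descriptors, focal-group estimates, convergence and log-likelihood.
#' @export
run_condition <- function(cond, estimators = c("gpcm", "mnrm", "irtree"),
                          seed = 1L, nq = NULL, tree_items = NULL,
                          truth_n = 500000, ...) {
  stopifnot(inherits(cond, "ers_condition"))
  estimators <- match.arg(estimators, c("gpcm", "mnrm", "irtree"),
                          several.ok = TRUE)
  items <- make_item_set(cond$base_thresholds, n_items = cond$n_items)
  gen_items <- items
  if (cond$generator == "irtree") {
    if (is.null(tree_items)) {
      tree_items <- derive_irtree_truth(
        items, n_per_group = truth_n, seed = substream_seeds(seed, 1L), nq = nq
      )
    }
    gen_items <- tree_items
  }
  seeds <- matrix(substream_seeds(seed + 1L, 2L * cond$n_reps), ncol = 2L)
  reps <- purrr::map_dfr(seq_len(cond$n_reps), function(r) {
    persons <- sample_persons(cond$n_per_group,
                              delta_ers = if (cond$generator == "gpcm") 0 else cond$delta_ers,
                              seed = seeds[r, 1L])
    dat <- simulate_responses(persons, gen_items, cond$generator,
                              seed = seeds[r, 2L])
    purrr::map_dfr(estimators, function(est) {
      fit <- tryCatch(
        fit_ers(dat, model = est, nq = nq, ...),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(tibble::tibble(
          rep = r, estimator = est, converged = FALSE,
          mean_sub = NA_real_, var_sub = NA_real_, mean_ers = NA_real_,
          cov_sub_ers = NA_real_, var_ers = NA_real_,
          loglik = NA_real_, n_iter = NA_integer_
        ))
      }
      tibble::tibble(
        rep = r, estimator = est, converged = fit$converged,
        mean_sub = fit$focal$mean_sub, var_sub = fit$focal$var_sub,
        mean_ers = fit$focal$mean_ers, cov_sub_ers = fit$focal$cov_sub_ers,
        var_ers = fit$focal$var_ers,
        loglik = fit$loglik, n_iter = fit$n_iter
      )
    })
  })
  dplyr::bind_cols(
    tibble::tibble(
      generator = cond$generator, delta_ers = cond$delta_ers,
      n_items = cond$n_items, base = base_label(cond$base_thresholds)
    )[rep(1L, nrow(reps)), ],
    reps
  )
}

#' Summarise focal-group bias over replications
#'
#' Bias is the mean over converged replications of (focal estimate minus
#' truth): truth 0 for the substantive mean, 1 for the substantive
#' variance.  Monte-Carlo standard errors accompany every bias, and a
#' cell is flagged as substantially biased when `|bias|` exceeds both
#' `3 * mc_se` and 0.05.
#'
#' @param results Output of [run_condition()] (rows of several
#'   conditions may be bound together).
#' @return A tibble of class `"ers_bias"`, one row per condition x
#'   estimator.
#' @export
bias_table <- function(results) {
  need <- c("generator", "delta_ers", "n_items", "base", "estimator",
            "converged", "mean_sub", "var_sub")
  miss <- setdiff(need, names(results))
  if (length(miss)) {
    abort(paste0("`results` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  out <- results |>
    dplyr::group_by(.data$generator, .data$delta_ers, .data$n_items,
                    .data$base, .data$estimator) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_converged = sum(.data$converged, na.rm = TRUE),
      mu_bias = mean(.data$mean_sub[.data$converged]) - 0,
      mu_mc_se = stats::sd(.data$mean_sub[.data$converged]) /
        sqrt(sum(.data$converged)),
      var_bias = mean(.data$var_sub[.data$converged]) - 1,
      var_mc_se = stats::sd(.data$var_sub[.data$converged]) /
        sqrt(sum(.data$converged)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mu_flag = abs(.data$mu_bias) > 3 * .data$mu_mc_se & abs(.data$mu_bias) > 0.05,
      var_flag = abs(.data$var_bias) > 3 * .data$var_mc_se & abs(.data$var_bias) > 0.05
    )
  class(out) <- c("ers_bias", class(out))
  out
}

#' Probability-curve report contrasting the nominal and IRTree families
#'
#' Numerically reproduces, for the item-set's average item (item
#' parameters averaged over the set, the usual way such probability
#' curves are displayed for a set of similar items), (a) agreement probability as
#' a function of ERS at several substantive-trait levels, (b) the
#' probability of the extreme-agreement category given an extreme
#' response, and (c) the four category-probability curves at a fixed
#' substantive trait of 0.
#'
#' @param mnrm_items Nominal-model item table.
#' @param tree_items Matched IRTree item table (typically
#'   [derive_irtree_truth()] of `mnrm_items`); must have the same number
#'   of items.
#' @param theta1_levels Substantive-trait levels for the agreement and
#'   conditional curves.
#' @param theta2 ERS grid.
#' @return A tibble of class `"ers_curves"` with columns `measure`,
#'   `model`, `theta1`, `theta2`, `category`, `prob`.
#' @export
curves_report <- function(mnrm_items, tree_items,
                          theta1_levels = c(-2, -1, 0, 1, 2),
                          theta2 = seq(-3, 3, length.out = 121)) {
  check_mnrm_items(mnrm_items, "mnrm_items")
  check_tree_items(tree_items, "tree_items")
  if (nrow(mnrm_items) != nrow(tree_items)) {
    abort("`mnrm_items` and `tree_items` must have the same number of items.")
  }
  avg_item <- function(items) {
    out <- items[1, ]
    for (cn in setdiff(names(items), "item")) out[[cn]] <- mean(items[[cn]])
    out
  }
  mnrm_avg <- avg_item(mnrm_items)
  tree_avg <- avg_item(tree_items)
  avg_probs <- function(model, theta) {
    prob_matrix(model, if (model == "mnrm") mnrm_avg else tree_avg, 1L, theta)
  }
  rows <- list()
  for (t1 in theta1_levels) {
    theta <- cbind(t1, theta2)
    for (model in c("mnrm", "irtree")) {
      p <- avg_probs(model, theta)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        measure = "agreement", model = model, theta1 = t1, theta2 = theta2,
        category = NA_integer_, prob = p[, 3L] + p[, 4L]
      )
      rows[[length(rows) + 1L]] <- tibble::tibble(
        measure = "conditional_extreme", model = model, theta1 = t1,
        theta2 = theta2, category = NA_integer_,
        prob = p[, 4L] / (p[, 1L] + p[, 4L])
      )
    }
  }
  theta0 <- cbind(0, theta2)
  for (model in c("mnrm", "irtree")) {
    p <- avg_probs(model, theta0)
    for (k in 1:4) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        measure = "category", model = model, theta1 = 0, theta2 = theta2,
        category = k, prob = p[, k]
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ers_curves", class(out))
  out
}

#' Configuration for a full simulation study
#'
#' @param preset `"smoke"` (5 reps, 200 per group), `"desk"` (100 reps,
#'   1000 per group) or `"full"` (500 reps, 1000 per group).
#' @param generators,n_items_set,bases,delta_set Grid axes; defaults
#'   reproduce the core 12 + 4 condition design.
#' @param estimators Families fit to every generated data set.
#' @param seed Root seed for the whole study.
#' @param nq Quadrature nodes per dimension.
#' @param truth_n IRTree truth-derivation sample size per group.
#' @param out_dir Optional directory for per-cell CSV checkpoints and
#'   the manifest.
#' @param with_curves Also compute the probability-curve reports (needs
#'   an IRTree truth derivation per threshold base)?
#' @param ... Overrides of individual fields.
#' @return A named list of class `"ers_config"`.
#' @export
study_config <- function(preset = c("desk", "smoke", "full"),
                         generators = c("gpcm", "mnrm", "irtree"),
                         n_items_set = c(10, 20),
                         bases = list(c(-1, 0, 1), c(0, 1, 2)),
                         delta_set = c(-1, 0, 1),
                         estimators = c("gpcm", "mnrm", "irtree"),
                         seed = 1L, nq = NULL, truth_n = 500000,
                         out_dir = NULL, with_curves = TRUE, ...) {
  preset <- match.arg(preset)
  sizes <- switch(preset,
    smoke = list(n_reps = 5L, n_per_group = 200L),
    desk = list(n_reps = 100L, n_per_group = 1000L),
    full = list(n_reps = 500L, n_per_group = 1000L)
  )
  cfg <- c(
    list(
      preset = preset, generators = generators, n_items_set = n_items_set,
      bases = bases, delta_set = delta_set, estimators = estimators,
      seed = as.integer(seed), nq = nq, truth_n = truth_n,
      out_dir = out_dir, with_curves = with_curves
    ),
    sizes
  )
  cfg <- modifyList(cfg, list(...))
  structure(cfg, class = "ers_config")
}

#' Run the full generator x condition x estimator study
#'
#' Orchestrates the complete cross design: builds the item sets, derives
#' the IRTree truth once per (items, thresholds) cell (from the zero
#' ERS-shift configuration, since item parameters are population
#' quantities), runs every condition under every estimator, and collects
#' the bias tables, curve reports and a manifest of all seeds.  When
#' `config$out_dir` is set, each cell is checkpointed to CSV and
#' finished cells are skipped on re-run.
#'
#' @param config An [study_config()] list.
#' @return A list of class `"ers_study"` with elements `results` (per
#'   replication), `bias` (an `"ers_bias"` table), `curves` (one
#'   `"ers_curves"` report per threshold base, 10-item sets) and
#'   `manifest`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "ers_config"))
  # the control generator carries no ERS, so it contributes one cell per
  # (items, thresholds) combination regardless of the delta grid
  cells_ers <- expand.grid(
    generator = setdiff(config$generators, "gpcm"),
    n_items = config$n_items_set,
    base_id = seq_along(config$bases),
    delta_ers = config$delta_set,
    stringsAsFactors = FALSE
  )
  cells_ctrl <- if ("gpcm" %in% config$generators) {
    expand.grid(
      generator = "gpcm", n_items = config$n_items_set,
      base_id = seq_along(config$bases), delta_ers = 0,
      stringsAsFactors = FALSE
    )
  }
  cells <- rbind(cells_ctrl, cells_ers)
  cell_seeds <- substream_seeds(config$seed, nrow(cells))
  truths <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    cell <- cells[ci, ]
    base <- config$bases[[cell$base_id]]
    tag <- paste0(
      "cell_", cell$generator, "_J", cell$n_items, "_b", cell$base_id,
      "_d", cell$delta_ers
    )
    if (!is.null(out_dir)) {
      fp <- file.path(out_dir, paste0(tag, ".csv"))
      if (file.exists(fp)) {
        return(readr::read_csv(fp, show_col_types = FALSE))
      }
    }
    tree <- NULL
    if (cell$generator == "irtree") {
      key <- paste0("J", cell$n_items, "_b", cell$base_id)
      if (is.null(truths[[key]])) {
        truths[[key]] <<- derive_irtree_truth(
          make_item_set(base, n_items = cell$n_items),
          n_per_group = config$truth_n, delta_ers = 0,
          seed = config$seed + cell$base_id * 1000L + cell$n_items,
          nq = config$nq
        )
      }
      tree <- truths[[key]]
    }
    cond <- condition_spec(
      generator = cell$generator, n_items = cell$n_items,
      base_thresholds = base, delta_ers = cell$delta_ers,
      n_per_group = config$n_per_group, n_reps = config$n_reps
    )
    res <- run_condition(cond, estimators = config$estimators,
                         seed = cell_seeds[ci], nq = config$nq,
                         tree_items = tree)
    if (!is.null(out_dir)) {
      readr::write_csv(res, file.path(out_dir, paste0(tag, ".csv")))
    }
    res
  })
  curves <- if (!isTRUE(config$with_curves)) list() else
    lapply(seq_along(config$bases), function(bi) {
    items <- make_item_set(config$bases[[bi]], n_items = min(config$n_items_set))
    key <- paste0("J", min(config$n_items_set), "_b", bi)
    tree <- truths[[key]]
    if (is.null(tree)) {
      tree <- derive_irtree_truth(
        items, n_per_group = config$truth_n, delta_ers = 0,
        seed = config$seed + bi * 1000L + min(config$n_items_set),
        nq = config$nq
      )
    }
    curves_report(items, tree)
  })
  if (length(curves)) {
    names(curves) <- vapply(config$bases, base_label, character(1L))
  }
  manifest <- list(
    config = unclass(config),
    cell_seeds = setNames(
      cell_seeds,
      paste0(cells$generator, "_J", cells$n_items, "_b", cells$base_id,
             "_d", cells$delta_ers)
    ),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("ersirt")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(out_dir)) {
    readr::write_csv(results, file.path(out_dir, "results.csv"))
    bt <- bias_table(results)
    readr::write_csv(bt, file.path(out_dir, "bias_table.csv"))
    if (requireNamespace("yaml", quietly = TRUE)) {
      yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    }
  }
  structure(
    list(
      results = results, bias = bias_table(results),
      curves = curves, manifest = manifest
    ),
    class = "ers_study"
  )
}
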