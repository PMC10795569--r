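# Shared fixtures.  Everything is generated in code with fixed seeds;
# the expensive IRTree truth derivations are cached per test run.

sym_items <- function(n_items = 10) make_item_set(c(-1, 0, 1), n_items = n_items)
asym_items <- function(n_items = 10) make_item_set(c(0, 1, 2), n_items = n_items)

# a standard symmetric single item (thresholds exactly -1, 0, 1; slopes 1.5)
std_item <- function() {
  ci <- intercepts_from_thresholds(c(-1, 0, 1), 1.5)
  tibble::tibble(item = 1L, a_sub = 1.5, a_ers = 1.5,
                 c1 = ci[1], c2 = ci[2], c3 = ci[3], c4 = ci[4])
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# IRTree truth derived from a moderate sample: large enough that the
# item parameters are stable to ~2 decimals, small enough for the test
# budget.
tree_truth <- function(base = c(-1, 0, 1), n_items = 10,
                       n_per_group = 30000) {
  key <- paste0("tree_", paste(base, collapse = "_"), "_", n_items)
  cached(key, derive_irtree_truth(
    make_item_set(base, n_items = n_items),
    n_per_group = n_per_group, seed = 4242
  ))
}

# small two-group data set for estimation tests
small_mnrm_data <- function(n_per_group = 300, delta_ers = 1, seed = 99,
                            items = sym_items(5)) {
  persons <- sample_persons(n_per_group, delta_ers = delta_ers, seed = seed)
  simulate_responses(persons, items, "mnrm", seed = seed + 1L)
}
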