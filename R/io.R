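# CSV interchange for response data.  Wide layout: one row per person
# (person, group, y_1..y_J); long layout: one row per response
# (person, group, item, response).  UTF-8, header row, "." decimal.

#' Read categorical response data from CSV
#'
#' @param path File path.
#' @param layout `"wide"` or `"long"`.
#' @param n_cat Number of categories `K` (responses outside `1..n_cat`
#'   are rejected with their cell positions).
#' @return A wide response tibble (`person`, `group` if present,
#'   `y_1..y_J`), ready for [fit_ers()].
#' @export
read_responses <- function(path, layout = c("wide", "long"), n_cat = 4) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (layout == "long") {
    need <- c("person", "item", "response")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
      abort(paste0("long layout needs column(s): ", paste(miss, collapse = ", ")))
    }
    bad <- which(!is.na(raw$response) &
                   !(raw$response %in% seq_len(n_cat)))
    if (length(bad)) {
      abort(paste0(
        "responses outside 1..", n_cat, " at row(s): ",
        paste(utils::head(bad, 5L), collapse = ", ")
      ))
    }
    wide <- raw |>
      dplyr::mutate(item = paste0("y_", .data$item)) |>
      tidyr::pivot_wider(names_from = "item", values_from = "response")
    return(wide)
  }
  nm <- names(raw)
  ycols <- grep("^(y|item)_", nm, value = TRUE)
  if (!length(ycols)) {
    ycols <- setdiff(nm, c("person", "id", "group"))
  }
  if (!length(ycols)) abort("no item columns found.")
  for (cn in ycols) {
    v <- raw[[cn]]
    bad <- which(!is.na(v) & !(v %in% seq_len(n_cat)))
    if (length(bad)) {
      abort(paste0(
        "responses outside 1..", n_cat, " in column ", cn,
        ", row(s): ", paste(utils::head(bad, 5L), collapse = ", ")
      ))
    }
  }
  out <- raw
  if ("id" %in% nm && !"person" %in% nm) {
    out <- dplyr::rename(out, person = "id")
  }
  names(out)[match(ycols, names(out))] <- paste0("y_", seq_along(ycols))
  out
}

#' Write response data to CSV
#'
#' @param data Wide response tibble (as produced by
#'   [simulate_responses()]).
#' @param path File path.
#' @param layout `"wide"` (one row per person) or `"long"` (one row per
#'   response).
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "long") {
    data <- data |>
      tidyr::pivot_longer(
        dplyr::starts_with("y_"),
        names_to = "item", values_to = "response",
        names_prefix = "y_", names_transform = as.integer
      )
  }
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
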