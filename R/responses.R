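# Responses live in a wide tibble: one row per respondent, a `respondent_id`
# column, and one column per item. Cell semantics:
#   substantive code / integer  -> answered
#   -818                        -> declined ("prefer not to answer")
#   -121                        -> "do not know"
#   NA                          -> absent if the item was presented,
#                                  rule-skipped otherwise (derived from the
#                                  instrument's skip rules)
# Multi-choice items are character columns of ";"-separated codes ("1;3"),
# with "-818"/"-121" sentinels.

is_multi_col <- function(x) is.character(x)

item_column <- function(responses, item_id, n) {
  if (item_id %in% names(responses)) responses[[item_id]] else rep(NA_integer_, n)
}

answered_cells <- function(x) {
  if (is_multi_col(x)) {
    !is.na(x) & !x %in% c("-818", "-121")
  } else {
    !is.na(x) & x != CODE_DECLINED & x != CODE_UNKNOWN
  }
}

responded_cells <- function(x) {
  if (is_multi_col(x)) !is.na(x) else !is.na(x)
}

parse_multi <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(v) as.integer(v[nzchar(v)]))
}

# Logical n x K matrix: was each item presented to each respondent?
# Rules are applied in instrument order of their triggers, so a rule whose
# trigger was itself rule-skipped (or not answered) never fires.
presented_matrix <- function(spec, responses) {
  n <- nrow(responses)
  ids <- spec$items$item_id
  pres <- matrix(TRUE, nrow = n, ncol = length(ids),
                 dimnames = list(NULL, ids))
  if (n == 0L || length(spec$rules) == 0L) return(pres)
  ord <- order(rule_trigger_positions(spec))
  for (r in spec$rules[ord]) {
    x <- item_column(responses, r$trigger_item, n)
    if (is_multi_col(x)) {
      hits <- purrr::map_lgl(parse_multi(x), ~ any(.x %in% r$trigger_codes))
    } else {
      hits <- x %in% r$trigger_codes
    }
    fired <- pres[, r$trigger_item] & answered_cells(x) & hits
    if (any(fired)) pres[fired, r$skipped_items] <- FALSE
  }
  pres
}

#' Which items should each respondent have been shown?
#'
#' A pure function of the instrument and the answers: items downstream of a
#' triggered skip rule are excluded; everything else is presented. Adding a
#' triggering answer can only shrink the presented set.
#'
#' @param responses Wide response tibble (see [read_responses()]).
#' @param spec An `mhq_instrument`.
#' @return A tibble `respondent_id`, `item_id`, `presented`.
#' @export
presented_items <- function(responses, spec) {
  pres <- presented_matrix(spec, responses)
  tibble(
    respondent_id = rep(responses$respondent_id, times = ncol(pres)),
    item_id = rep(colnames(pres), each = nrow(pres)),
    presented = as.vector(pres)
  ) |>
    arrange(match(.data$respondent_id, responses$respondent_id),
            match(.data$item_id, spec$items$item_id))
}

# Character n x K matrix of per-cell statuses:
# answered / declined / unknown / rule_skipped / absent.
status_matrix <- function(spec, responses) {
  n <- nrow(responses)
  pres <- presented_matrix(spec, responses)
  out <- matrix("absent", nrow = n, ncol = ncol(pres),
                dimnames = dimnames(pres))
  for (id in colnames(pres)) {
    x <- item_column(responses, id, n)
    if (is_multi_col(x)) {
      st <- ifelse(is.na(x), "absent",
            ifelse(x == "-818", "declined",
            ifelse(x == "-121", "unknown", "answered")))
    } else {
      st <- ifelse(is.na(x), "absent",
            ifelse(x == CODE_DECLINED, "declined",
            ifelse(x == CODE_UNKNOWN, "unknown", "answered")))
    }
    st[!pres[, id]] <- "rule_skipped"
    out[, id] <- st
  }
  out
}

# Numeric criterion values for classifiers: answered -> value; presented but
# declined/unknown/absent -> NA (missing for the tri-state logic);
# rule-skipped -> 0 ("criterion not endorsed": the respondent screened out).
crit_values <- function(spec, responses) {
  n <- nrow(responses)
  pres <- presented_matrix(spec, responses)
  single_ids <- spec$items$item_id[spec$items$response_kind != "multi_choice"]
  vals <- matrix(NA_real_, nrow = n, ncol = length(single_ids),
                 dimnames = list(NULL, single_ids))
  for (id in single_ids) {
    x <- item_column(responses, id, n)
    v <- ifelse(answered_cells(x), as.numeric(x), NA_real_)
    v[!pres[, id]] <- 0
    vals[, id] <- v
  }
  vals
}

#' Check responses against an instrument
#'
#' Violations are data, not exceptions: illegal substantive codes, and
#' answers recorded on items that a compliant respondent was never shown
#' (downstream of a triggered skip rule).
#'
#' @param responses Wide response tibble.
#' @param spec An `mhq_instrument`.
#' @return A tibble `respondent_id`, `item_id`, `problem`, `detail`;
#'   zero rows when the responses are consistent with the instrument.
#' @export
validate_responses <- function(responses, spec) {
  n <- nrow(responses)
  pres <- presented_matrix(spec, responses)
  out <- list()
  for (id in spec$items$item_id) {
    if (!id %in% names(responses)) next
    x <- responses[[id]]
    ans <- answered_cells(x)
    legal <- legal_codes(spec, id)
    if (item_kind(spec, id) == "multi_choice") {
      bad <- ans & purrr::map_lgl(parse_multi(x), ~ length(.x) == 0L ||
                                    any(!.x %in% legal))
    } else {
      bad <- ans & !(x %in% legal)
    }
    if (any(bad)) {
      out[[length(out) + 1L]] <- tibble(
        respondent_id = responses$respondent_id[bad], item_id = id,
        problem = "illegal_code",
        detail = sprintf("code %s not in coding of %s", as.character(x[bad]), id)
      )
    }
    in_skip <- ans & !pres[, id]
    if (any(in_skip)) {
      out[[length(out) + 1L]] <- tibble(
        respondent_id = responses$respondent_id[in_skip], item_id = id,
        problem = "answered_in_skip",
        detail = sprintf("item %s answered despite a triggered skip rule", id)
      )
    }
  }
  if (length(out) == 0L) {
    tibble(respondent_id = character(), item_id = character(),
           problem = character(), detail = character())
  } else {
    bind_rows(out)
  }
}

#' Completion status of each respondent
#'
#' `complete`: every presented item carries a response (an answer, a refusal
#' or "do not know" -- voluntary refusal counts as responding).
#' `not_started`: no response to any item. Otherwise `partial`.
#'
#' @inheritParams validate_responses
#' @return A tibble `respondent_id`, `completion` (factor).
#' @export
completion_status <- function(responses, spec) {
  n <- nrow(responses)
  pres <- presented_matrix(spec, responses)
  responded <- matrix(FALSE, nrow = n, ncol = ncol(pres),
                      dimnames = dimnames(pres))
  for (id in colnames(pres)) {
    responded[, id] <- responded_cells(item_column(responses, id, n))
  }
  any_resp <- rowSums(responded) > 0L
  all_pres_resp <- rowSums(pres & !responded) == 0L
  tibble(
    respondent_id = responses$respondent_id,
    completion = factor(
      ifelse(!any_resp, "not_started",
             ifelse(all_pres_resp, "complete", "partial")),
      levels = c("complete", "partial", "not_started")
    )
  )
}

#' Read a response table
#'
#' Wide layout: one row per respondent, one column per item, sentinel codes
#' for refusal and "do not know". Long layout: columns `respondent_id`,
#' `item_id`, `value`, pivoted to wide on read.
#'
#' @param path Delimited text file (tab or comma inferred from extension).
#' @param spec An `mhq_instrument`; column types (including multi-choice
#'   character columns) follow its item definitions.
#' @param layout `"wide"` or `"long"`.
#' @param declined,unknown Sentinel codes used in the file.
#' @return A wide response tibble.
#' @export
read_responses <- function(path, spec, layout = c("wide", "long"),
                           declined = CODE_DECLINED, unknown = CODE_UNKNOWN) {
  layout <- match.arg(layout)
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (layout == "long") {
    for (col in c("respondent_id", "item_id", "value")) {
      if (!col %in% names(raw)) {
        abort(sprintf("long response file %s: missing column '%s'", path, col))
      }
    }
    raw <- tidyr::pivot_wider(raw, id_cols = "respondent_id",
                              names_from = "item_id", values_from = "value")
  }
  if (!"respondent_id" %in% names(raw)) {
    abort(sprintf("response file %s: missing column 'respondent_id'", path))
  }
  out <- tibble(respondent_id = as.character(raw$respondent_id))
  for (id in intersect(spec$items$item_id, names(raw))) {
    x <- raw[[id]]
    if (item_kind(spec, id) == "multi_choice") {
      x <- dplyr::if_else(x %in% as.character(c(declined, unknown)),
                          dplyr::if_else(x == as.character(declined),
                                         "-818", "-121"), x)
      out[[id]] <- x
    } else {
      v <- suppressWarnings(as.integer(x))
      v[which(v == declined)] <- CODE_DECLINED
      v[which(v == unknown)] <- CODE_UNKNOWN
      out[[id]] <- v
    }
  }
  out
}

#' Write a response table
#'
#' @param responses Wide response tibble.
#' @param path Output path (`.csv` writes comma-delimited, otherwise tab).
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "long") {
    responses <- responses |>
      mutate(across(-"respondent_id", as.character)) |>
      tidyr::pivot_longer(-"respondent_id", names_to = "item_id",
                          values_to = "value", values_drop_na = TRUE)
  }
  if (grepl("\\.csv$", path)) {
    readr::write_csv(responses, path, progress = FALSE)
  } else {
    readr::write_tsv(responses, path, progress = FALSE)
  }
  invisible(path)
}
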