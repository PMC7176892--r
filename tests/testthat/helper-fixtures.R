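# Shared fixtures: a single-row response builder, a reduced instrument for
# exhaustive questionnaire-walk enumeration, and small cohorts.

# one respondent, named item values; unnamed items are simply not in the
# table (treated as absent)
resp <- function(..., id = "r1") {
  vals <- list(...)
  out <- tibble::tibble(respondent_id = id)
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  out
}

# a wide table of several respondents from a list of named-value lists
resp_many <- function(rows) {
  purrr::imap(rows, function(r, i) do.call(resp, c(r, list(id = sprintf("r%d", i))))) |>
    dplyr::bind_rows()
}

# reduced branching instrument (7 items, 2 gates) for exhaustive walk
# enumeration
mini_instrument <- function() {
  yn <- c(no = 0L, yes = 1L)
  items <- dplyr::bind_rows(
    mhq_item("s1", "depression", "screen 1", "single_choice", coding = yn),
    mhq_item("s2", "depression", "screen 2", "single_choice", coding = yn),
    mhq_item("d1", "depression", "detail 1", "single_choice", coding = yn),
    mhq_item("d2", "depression", "detail 2", "single_choice", coding = yn),
    mhq_item("g1", "anxiety", "gate 2", "single_choice",
             coding = c(a = 0L, b = 1L, c = 2L)),
    mhq_item("e1", "anxiety", "detail 3", "single_choice", coding = yn),
    mhq_item("z1", "wellbeing", "always asked", "single_choice", coding = yn)
  )
  rules <- list(
    skip_rule("s1", 1L, "s2"),
    skip_rule("s2", 0L, c("d1", "d2")),
    skip_rule("g1", c(0L, 2L), "e1")
  )
  mhq_instrument(items, rules, version = "mini-1.0")
}

# Independent questionnaire-walk oracle: walk the items in order, keeping a
# skip set; at each presented item take the given answer and apply any rule
# it triggers. Returns the presented item ids.
oracle_walk <- function(spec, answers) {
  skipped <- character()
  presented <- character()
  for (id in spec$items$item_id) {
    if (id %in% skipped) next
    presented <- c(presented, id)
    if (!id %in% names(answers)) next
    a <- answers[[id]]
    if (is.na(a)) next
    for (r in spec$rules) {
      if (r$trigger_item == id && a %in% r$trigger_codes) {
        skipped <- union(skipped, r$skipped_items)
      }
    }
  }
  presented
}

# Enumerate every substantive answer sequence of a (small) instrument by
# walking it: at each presented item branch over all legal codes. Returns a
# list of named integer vectors (answers on presented items only).
enumerate_walks <- function(spec) {
  ids <- spec$items$item_id
  out <- list()
  recurse <- function(i, answers, skipped) {
    while (i <= length(ids) && ids[[i]] %in% skipped) i <- i + 1L
    if (i > length(ids)) {
      out[[length(out) + 1L]] <<- answers
      return(invisible())
    }
    id <- ids[[i]]
    for (code in legal_codes_t(spec, id)) {
      sk <- skipped
      for (r in spec$rules) {
        if (r$trigger_item == id && code %in% r$trigger_codes) {
          sk <- union(sk, r$skipped_items)
        }
      }
      a2 <- answers
      a2[[id]] <- code
      recurse(i + 1L, a2, sk)
    }
  }
  recurse(1L, c(), character())
  out
}

legal_codes_t <- function(spec, id) {
  i <- match(id, spec$items$item_id)
  co <- spec$items$coding[[i]]
  if (!is.null(co)) unname(co) else spec$items$domain[[i]]
}

answers_to_responses <- function(spec, answers, id = "r1") {
  out <- tibble::tibble(respondent_id = id)
  for (it in spec$items$item_id) {
    out[[it]] <- if (it %in% names(answers)) as.integer(answers[[it]]) else NA_integer_
  }
  out
}

# small cached cohorts so several test files can share one generation
.test_env <- new.env(parent = emptyenv())

perfect_cohort <- function(n = 2000, seed = 101) {
  key <- sprintf("perfect_%d_%d", n, seed)
  if (is.null(.test_env[[key]])) {
    cfg <- cohort_config(
      n = n, seed = seed,
      emission_fidelity = list(sensitivity = 1, specificity = 1),
      decline_rate = 0, partial_rate = 0
    )
    .test_env[[key]] <- generate_cohort(cfg)
  }
  .test_env[[key]]
}

default_cohort <- function(n = 1500, seed = 202) {
  key <- sprintf("default_%d_%d", n, seed)
  if (is.null(.test_env[[key]])) {
    .test_env[[key]] <- generate_cohort(cohort_config(n = n, seed = seed))
  }
  .test_env[[key]]
}
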