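#' Define a questionnaire item
#'
#' Items are the atoms of an instrument: a coded question with a response
#' kind, a substantive coding (for choice items) or an integer range, and an
#' optional enumeration domain used by the synthetic generator and by
#' exhaustive oracles.
#'
#' @param item_id Unique identifier (character scalar).
#' @param section One of the instrument sections (see `mhq_sections()`).
#' @param prompt Question text. The bundled default instrument carries
#'   placeholder prompts; criteria logic binds to `item_id`, never to text.
#' @param response_kind One of `"single_choice"`, `"multi_choice"`,
#'   `"integer"`, `"duration"`. Duration items are integers in a stated unit
#'   (the unit belongs to the prompt and the ruleset threshold).
#' @param coding Named integer vector mapping labels to substantive codes
#'   (choice kinds only).
#' @param min,max Legal range for integer/duration kinds.
#' @param domain Optional integer vector: the enumeration support used when
#'   exhaustively enumerating response patterns (defaults to the coding for
#'   choice items and `min:max` for integers).
#' @return A one-row tibble suitable for `mhq_instrument()`.
#' @export
mhq_item <- function(item_id, section, prompt, response_kind,
                     coding = NULL, min = NA_integer_, max = NA_integer_,
                     domain = NULL) {
  stopifnot(is.character(item_id), length(item_id) == 1L)
  if (!section %in% MHQ_SECTIONS) {
    abort(sprintf("item '%s': unknown section '%s'", item_id, section))
  }
  if (!response_kind %in% RESPONSE_KINDS) {
    abort(sprintf("item '%s': unknown response_kind '%s'", item_id, response_kind))
  }
  if (response_kind %in% c("single_choice", "multi_choice")) {
    if (is.null(coding) || is.null(names(coding)) || any(names(coding) == "")) {
      abort(sprintf("item '%s': choice items need a fully named coding", item_id))
    }
    coding <- as.integer(coding) |> setNames(names(coding))
    if (anyDuplicated(coding)) {
      abort(sprintf("item '%s': duplicate codes in coding", item_id))
    }
    if (any(coding %in% c(CODE_DECLINED, CODE_UNKNOWN))) {
      abort(sprintf(
        "item '%s': coding collides with reserved decline/unknown codes", item_id
      ))
    }
    if (is.null(domain)) domain <- unname(coding)
  } else {
    if (is.na(min) || is.na(max) || min > max) {
      abort(sprintf("item '%s': integer items need min <= max", item_id))
    }
    if (is.null(domain)) domain <- seq.int(min, max)
  }
  tibble(
    item_id = item_id, section = section, prompt = prompt,
    response_kind = response_kind,
    coding = list(coding),
    min = as.integer(min), max = as.integer(max),
    domain = list(as.integer(domain))
  )
}

#' Define a skip rule
#'
#' A skip rule suppresses presentation of later items when its trigger item
#' is answered with one of the trigger codes. This is the branching device
#' of screening instruments: a negative screen routes the respondent past
#' the detailed block.
#'
#' @param trigger_item Item whose answer is examined.
#' @param trigger_codes Integer codes that fire the rule.
#' @param skipped_items Items suppressed when the rule fires; all must come
#'   after the trigger in instrument order.
#' @return A `skip_rule` list.
#' @export
skip_rule <- function(trigger_item, trigger_codes, skipped_items) {
  structure(
    list(
      trigger_item = trigger_item,
      trigger_codes = as.integer(trigger_codes),
      skipped_items = as.character(skipped_items)
    ),
    class = "skip_rule"
  )
}

#' Assemble and validate an instrument
#'
#' @param items Tibble of items from [mhq_item()] (row-bound), in
#'   presentation order.
#' @param rules List of [skip_rule()] objects.
#' @param version Version string stamped into outputs.
#' @return A validated `mhq_instrument`.
#' @export
mhq_instrument <- function(items, rules = list(), version = "unversioned") {
  spec <- structure(
    list(items = items, rules = rules, version = version),
    class = "mhq_instrument"
  )
  validate_instrument(spec)
  spec
}

#' @export
print.mhq_instrument <- function(x, ...) {
  cat(sprintf(
    "<mhq_instrument '%s': %d items in %d sections, %d skip rules>\n",
    x$version, nrow(x$items), length(unique(x$items$section)), length(x$rules)
  ))
  invisible(x)
}

#' Validate instrument invariants
#'
#' Checks item-id uniqueness, reserved-code disjointness, rule references,
#' forward-only (hence acyclic) skipping, and no self-triggering rules.
#' Errors name the offending item or rule.
#'
#' @param spec An `mhq_instrument`.
#' @return The spec, invisibly.
#' @export
validate_instrument <- function(spec) {
  items <- spec$items
  if (anyDuplicated(items$item_id)) {
    abort(sprintf(
      "duplicate item_id: %s",
      paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", ")
    ))
  }
  pos <- setNames(seq_len(nrow(items)), items$item_id)
  for (i in seq_along(spec$rules)) {
    r <- spec$rules[[i]]
    refs <- c(r$trigger_item, r$skipped_items)
    missing_ref <- setdiff(refs, items$item_id)
    if (length(missing_ref) > 0L) {
      abort(sprintf(
        "skip rule %d references missing item(s): %s",
        i, paste(missing_ref, collapse = ", ")
      ))
    }
    if (r$trigger_item %in% r$skipped_items) {
      abort(sprintf("skip rule %d: item '%s' triggers itself", i, r$trigger_item))
    }
    if (any(pos[r$skipped_items] <= pos[r$trigger_item])) {
      abort(sprintf(
        "skip rule %d: skipped items must follow trigger '%s' in instrument order",
        i, r$trigger_item
      ))
    }
  }
  invisible(spec)
}

#' @rdname mhq_item
#' @export
mhq_sections <- function() MHQ_SECTIONS

rule_trigger_positions <- function(spec) {
  pos <- setNames(seq_len(nrow(spec$items)), spec$items$item_id)
  vapply(spec$rules, function(r) pos[[r$trigger_item]], numeric(1))
}

item_domain <- function(spec, item_id) {
  spec$items$domain[[match(item_id, spec$items$item_id)]]
}

item_kind <- function(spec, item_id) {
  spec$items$response_kind[[match(item_id, spec$items$item_id)]]
}

legal_codes <- function(spec, item_id) {
  i <- match(item_id, spec$items$item_id)
  kind <- spec$items$response_kind[[i]]
  if (kind %in% c("single_choice", "multi_choice")) {
    unname(spec$items$coding[[i]])
  } else {
    seq.int(spec$items$min[[i]], spec$items$max[[i]])
  }
}

#' Write an instrument to a structured-text (YAML) file
#'
#' @param spec An `mhq_instrument`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(spec, path) {
  items <- purrr::pmap(spec$items, function(item_id, section, prompt,
                                            response_kind, coding, min, max,
                                            domain) {
    it <- list(
      item_id = item_id, section = section, prompt = prompt,
      response_kind = response_kind
    )
    if (!is.null(coding)) it$coding <- as.list(coding)
    if (!is.na(min)) it$min <- min
    if (!is.na(max)) it$max <- max
    it$domain <- domain
    it
  })
  rules <- purrr::map(spec$rules, function(r) {
    list(
      trigger_item = r$trigger_item,
      trigger_codes = r$trigger_codes,
      skipped_items = r$skipped_items
    )
  })
  yaml::write_yaml(
    list(
      version = spec$version,
      reserved = list(declined = CODE_DECLINED, unknown = CODE_UNKNOWN),
      items = items, rules = rules
    ),
    path
  )
  invisible(path)
}

#' Load an instrument from a structured-text (YAML) file
#'
#' Parses and validates; parse problems name the offending field, dangling
#' or backward skip rules raise validation errors naming the rule.
#'
#' @param path Path to an instrument file, or `"default"` for the bundled
#'   MHQ-like instrument.
#' @return A validated `mhq_instrument`.
#' @export
read_instrument <- function(path) {
  if (identical(path, "default")) return(default_instrument())
  if (!file.exists(path)) abort(sprintf("instrument file not found: %s", path))
  raw <- yaml::read_yaml(path)
  for (field in c("version", "items")) {
    if (is.null(raw[[field]])) {
      abort(sprintf("instrument file %s: missing field '%s'", path, field))
    }
  }
  items <- purrr::map(raw$items, function(it) {
    for (field in c("item_id", "section", "response_kind")) {
      if (is.null(it[[field]])) {
        abort(sprintf("instrument file %s: item missing field '%s'", path, field))
      }
    }
    mhq_item(
      item_id = it$item_id, section = it$section,
      prompt = it$prompt %||% "", response_kind = it$response_kind,
      coding = if (!is.null(it$coding)) unlist(it$coding),
      min = it$min %||% NA_integer_, max = it$max %||% NA_integer_,
      domain = if (!is.null(it$domain)) unlist(it$domain)
    )
  }) |> bind_rows()
  rules <- purrr::map(raw$rules %||% list(), function(r) {
    for (field in c("trigger_item", "trigger_codes", "skipped_items")) {
      if (is.null(r[[field]])) {
        abort(sprintf("instrument file %s: rule missing field '%s'", path, field))
      }
    }
    skip_rule(r$trigger_item, unlist(r$trigger_codes), unlist(r$skipped_items))
  })
  mhq_instrument(items, rules, version = raw$version)
}

#' Export the data dictionary of an instrument
#'
#' One row per item and code (choice items) or per item with its legal range
#' (integer items), plus the reserved decline/unknown sentinels.
#'
#' @param spec An `mhq_instrument`.
#' @return A tibble with columns `item_id`, `section`, `response_kind`,
#'   `code`, `label`.
#' @export
data_dictionary <- function(spec) {
  rows <- purrr::pmap(spec$items, function(item_id, section, prompt,
                                           response_kind, coding, min, max,
                                           domain) {
    if (!is.null(coding)) {
      tibble(
        item_id = item_id, section = section, response_kind = response_kind,
        code = as.integer(unname(coding)), label = names(coding)
      )
    } else {
      tibble(
        item_id = item_id, section = section, response_kind = response_kind,
        code = NA_integer_, label = sprintf("integer %d..%d", min, max)
      )
    }
  })
  reserved <- tibble(
    item_id = "(all)", section = "(reserved)", response_kind = "(sentinel)",
    code = c(CODE_DECLINED, CODE_UNKNOWN),
    label = c("prefer not to answer", "do not know")
  )
  bind_rows(rows, reserved)
}
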