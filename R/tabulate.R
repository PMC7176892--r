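# Descriptive surfaces: row-conditional comorbidity between syndromes,
# prevalence of self-reported professional diagnoses, characteristics by
# lifetime-syndrome stratum or mood group, sex stratification, and a
# label-matched join against a user-supplied external prevalence table.
# Denominators are always explicit: cross-tabs use pairwise complete cases
# (both statuses assessable), characteristics tables per-cell complete
# cases, and counts always accompany percentages.

crosstab_syndromes <- function() c(SYNDROMES[SYNDROMES != "addiction"],
                                   "addiction", "bipolar")

#' Row-conditional comorbidity cross-tab
#'
#' For each ordered pair of syndromes, the percentage of respondents with
#' the row syndrome who also meet the column syndrome, among respondents
#' assessable on both. Overlapping membership is expected; pair counts are
#' symmetric, denominators are not.
#'
#' @param phenotypes An `mhq_phenotypes` tibble from [classify_all()].
#' @param syndromes Character vector of status columns to cross-tabulate.
#' @return An `mhq_crosstab` with `counts`, `denominators`, `row_totals`
#'   and `row_pct` matrices.
#' @export
comorbidity_crosstab <- function(phenotypes, syndromes = crosstab_syndromes()) {
  M <- sapply(syndromes, function(s) {
    st <- phenotypes[[s]]
    ifelse(st == "unassessable", NA, st == "met")
  })
  if (nrow(phenotypes) == 1L) M <- matrix(M, nrow = 1L,
                                          dimnames = list(NULL, syndromes))
  if (nrow(phenotypes) == 0L) M <- matrix(NA, nrow = 0L, ncol = length(syndromes),
                                          dimnames = list(NULL, syndromes))
  k <- length(syndromes)
  counts <- denom <- matrix(0L, k, k, dimnames = list(syndromes, syndromes))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- !is.na(M[, i]) & !is.na(M[, j])
      counts[i, j] <- sum(M[ok, i] & M[ok, j])
      denom[i, j] <- sum(M[ok, i])
    }
  }
  row_pct <- ifelse(denom > 0L, 100 * counts / denom, NA_real_)
  structure(
    list(
      syndromes = syndromes, counts = counts, denominators = denom,
      row_totals = diag(denom), row_pct = row_pct, n = nrow(phenotypes)
    ),
    class = "mhq_crosstab"
  )
}

#' @export
print.mhq_crosstab <- function(x, digits = 1, ...) {
  cat(sprintf("Comorbidity cross-tab (%d respondents)\n", x$n))
  cat("Row percentages (share of row syndrome also meeting column):\n")
  print(round(x$row_pct, digits))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a comorbidity cross-tab into a long tibble
#'
#' @param x An `mhq_crosstab`.
#' @param ... Unused.
#' @return A tibble `row_syndrome`, `col_syndrome`, `count`, `denominator`,
#'   `pct`.
#' @export
tidy.mhq_crosstab <- function(x, ...) {
  tidyr::expand_grid(row_syndrome = x$syndromes, col_syndrome = x$syndromes) |>
    mutate(
      count = as.vector(t(x$counts)),
      denominator = as.vector(t(x$denominators)),
      pct = as.vector(t(x$row_pct))
    )
}

#' Prevalence of self-reported professional diagnoses
#'
#' Per-category counts and percentages over respondents who answered the
#' tick-all diagnosis item, plus cumulative "one or more" and "two or more"
#' rows.
#'
#' @param phenotypes An `mhq_phenotypes` tibble.
#' @return A tibble `category`, `n`, `denominator`, `pct`.
#' @export
diagnosis_prevalence <- function(phenotypes) {
  dx_cols <- grep("^dx_", names(phenotypes), value = TRUE)
  dx_cols <- setdiff(dx_cols, "dx_answered")
  ok <- !is.na(phenotypes$dx_answered) & phenotypes$dx_answered
  denominator <- sum(ok)
  per_cat <- purrr::map(dx_cols, function(col) {
    tibble(
      category = sub("^dx_", "", col),
      n = sum(phenotypes[[col]][ok], na.rm = TRUE),
      denominator = denominator
    )
  }) |> bind_rows()
  cum <- tibble(
    category = c("one_or_more", "two_or_more"),
    n = c(sum(phenotypes$n_diagnoses[ok] >= 1L),
          sum(phenotypes$n_diagnoses[ok] >= 2L)),
    denominator = denominator
  )
  bind_rows(per_cat, cum) |>
    mutate(pct = ifelse(denominator > 0, 100 * n / denominator, NA_real_))
}

syndrome_strata <- function(phenotypes) {
  none <- status_known(phenotypes$depression) &
    !status_true(phenotypes$depression) &
    status_known(phenotypes$gad) & !status_true(phenotypes$gad) &
    status_known(phenotypes$unusual_experiences) &
    !status_true(phenotypes$unusual_experiences) &
    status_known(phenotypes$addiction) & !status_true(phenotypes$addiction)
  list(
    none_of_the_above = none,
    depression = status_true(phenotypes$depression),
    bipolar_affective_disorder = status_true(phenotypes$bipolar),
    gad = status_true(phenotypes$gad),
    unusual_experiences = status_true(phenotypes$unusual_experiences),
    addiction = status_true(phenotypes$addiction)
  )
}

mood_strata <- function(phenotypes) {
  out <- lapply(MOOD_GROUPS, function(g) {
    !is.na(phenotypes$mood_group) & phenotypes$mood_group == g
  })
  names(out) <- MOOD_GROUPS
  out
}

characteristic_specs <- function() {
  tribble_chr <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble(characteristic = m[, 1], column = m[, 2], kind = m[, 3])
  }
  tribble_chr(
    "female", "sex", "level:female",
    "aged_65_plus", "age_band", "level:65+",
    "degree_holder", "degree_holder", "logical",
    "most_deprived_quintile", "townsend_quintile", "level:5",
    "renter", "renter", "logical",
    "longstanding_illness", "longstanding_illness", "tri",
    "neuroticism_mean", "neuroticism_score", "mean",
    "childhood_adversity", "childhood_adversity", "tri",
    "adult_adversity", "adult_adversity", "tri",
    "trauma_exposure", "trauma_exposure", "tri",
    "loneliness", "loneliness", "tri",
    "social_isolation", "social_isolation", "tri",
    "ever_smoked", "ever_smoked", "tri",
    "ever_cannabis", "ever_cannabis", "tri",
    "physical_activity_met", "physical_activity_met", "tri"
  )
}

cell_stat <- function(x, kind) {
  if (kind == "logical") {
    ok <- !is.na(x)
    list(value = ifelse(any(ok), 100 * mean(x[ok]), NA_real_),
         n_used = sum(ok), statistic = "pct")
  } else if (kind == "tri") {
    ok <- !is.na(x) & x != "unassessable"
    list(value = ifelse(any(ok), 100 * mean(x[ok] == "met"), NA_real_),
         n_used = sum(ok), statistic = "pct")
  } else if (kind == "mean") {
    ok <- !is.na(x)
    list(value = ifelse(any(ok), mean(x[ok]), NA_real_),
         n_used = sum(ok), statistic = "mean")
  } else if (startsWith(kind, "level:")) {
    lev <- sub("^level:", "", kind)
    ok <- !is.na(x)
    list(value = ifelse(any(ok), 100 * mean(as.character(x[ok]) == lev),
                        NA_real_),
         n_used = sum(ok), statistic = "pct")
  } else {
    abort(sprintf("unknown characteristic kind '%s'", kind))
  }
}

#' Characteristics by lifetime-syndrome stratum or mood group
#'
#' For each stratum (respondents meeting each syndrome, a
#' "none of the above" stratum with none of depression, generalised
#' anxiety, unusual experiences or addiction, or the five mood groups),
#' the percentage or mean of each characteristic among members assessable
#' on that characteristic. Respondents may appear in several syndrome
#' strata. Denominators are reported per cell.
#'
#' @param phenotypes An `mhq_phenotypes` tibble.
#' @param risks An `mhq_risk` tibble from [derive_risk_profiles()].
#' @param strata `"syndrome"` (default) or `"mood"`.
#' @return An `mhq_strattable` tibble: `stratum`, `n_stratum`,
#'   `characteristic`, `statistic`, `value`, `n_used`.
#' @export
characteristics_by_stratum <- function(phenotypes, risks,
                                       strata = c("syndrome", "mood")) {
  strata <- match.arg(strata)
  joined <- left_join(as_tibble(phenotypes), as_tibble(risks),
                      by = "respondent_id")
  masks <- if (strata == "syndrome") syndrome_strata(phenotypes) else
    mood_strata(phenotypes)
  specs <- characteristic_specs()
  out <- purrr::imap(masks, function(mask, stratum) {
    sub <- joined[mask, , drop = FALSE]
    purrr::pmap(specs, function(characteristic, column, kind) {
      st <- cell_stat(sub[[column]], kind)
      tibble(
        stratum = stratum, n_stratum = sum(mask),
        characteristic = characteristic, statistic = st$statistic,
        value = st$value, n_used = st$n_used
      )
    }) |> bind_rows()
  }) |> bind_rows()
  structure(out, class = c("mhq_strattable", class(out)))
}

#' Syndrome prevalence stratified by sex
#'
#' Percentage of each syndrome (plus any syndrome) within women and men,
#' over respondents assessable on that syndrome.
#'
#' @param phenotypes An `mhq_phenotypes` tibble.
#' @param risks An `mhq_risk` tibble supplying `sex`.
#' @return An `mhq_strattable` tibble: `stratum` (sex), `syndrome`,
#'   `n_met`, `n_assessable`, `pct`.
#' @export
stratify_by_sex <- function(phenotypes, risks) {
  joined <- left_join(
    as_tibble(phenotypes),
    as_tibble(risks)[, c("respondent_id", "sex")],
    by = "respondent_id"
  )
  cols <- c(SYNDROMES, "bipolar")
  out <- purrr::map(c("female", "male"), function(sx) {
    sub <- joined[!is.na(joined$sex) & joined$sex == sx, , drop = FALSE]
    rows <- purrr::map(cols, function(s) {
      known <- status_known(sub[[s]])
      tibble(
        stratum = sx, syndrome = s,
        n_met = sum(status_true(sub[[s]])),
        n_assessable = sum(known),
        pct = ifelse(any(known), 100 * mean(sub[[s]][known] == "met"),
                     NA_real_)
      )
    }) |> bind_rows()
    any_row <- tibble(
      stratum = sx, syndrome = "any_syndrome",
      n_met = sum(sub$any_syndrome), n_assessable = nrow(sub),
      pct = ifelse(nrow(sub) > 0, 100 * mean(sub$any_syndrome), NA_real_)
    )
    bind_rows(rows, any_row)
  }) |> bind_rows()
  structure(out, class = c("mhq_strattable", class(out)))
}

#' Join an internal prevalence table to an external comparison table
#'
#' Label-matched full join (case- and whitespace-insensitive); categories
#' present on only one side are kept and listed in the `mismatches`
#' attribute, never silently dropped.
#'
#' @param internal Tibble with a `category` column (e.g. from
#'   [diagnosis_prevalence()]).
#' @param external User-supplied tibble with `category` and comparison
#'   columns (e.g. an external survey's prevalence estimates).
#' @return A joined tibble with attribute `mismatches`: a list with
#'   `internal_only` and `external_only` label vectors.
#' @export
join_external_comparison <- function(internal, external) {
  norm <- function(x) tolower(trimws(as.character(x)))
  internal <- internal |> mutate(.label = norm(.data$category))
  external <- external |> mutate(.label = norm(.data$category)) |>
    rename(category_external = "category")
  joined <- full_join(internal, external, by = ".label",
                      suffix = c("_internal", "_external")) |>
    mutate(category = dplyr::coalesce(.data$category,
                                      .data$category_external)) |>
    select(-".label", -"category_external")
  mismatches <- list(
    internal_only = setdiff(norm(internal$category), norm(external$category_external)),
    external_only = setdiff(norm(external$category_external), norm(internal$category))
  )
  attr(joined, "mismatches") <- mismatches
  joined
}

#' One-line cohort summary of a phenotype table
#'
#' @param x An `mhq_phenotypes` tibble.
#' @param ... Unused.
#' @return A one-row tibble: respondent count, per-syndrome met
#'   percentages over assessable respondents, any-syndrome percentage and
#'   the count of rows with any unassessable syndrome.
#' @export
glance.mhq_phenotypes <- function(x, ...) {
  pcts <- purrr::map(c(SYNDROMES, "bipolar"), function(s) {
    known <- status_known(x[[s]])
    setNames(
      tibble(ifelse(any(known), 100 * mean(x[[s]][known] == "met"), NA_real_)),
      paste0("pct_", s)
    )
  })
  bind_cols(
    tibble(n = nrow(x)), pcts,
    tibble(
      pct_any_syndrome = ifelse(nrow(x) > 0, 100 * mean(x$any_syndrome),
                                NA_real_),
      n_any_unassessable = sum(x$any_unassessable)
    )
  )
}
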