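#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a comorbidity cross-tab
#'
#' Row-conditional percentages as a tile map: each cell is the share of
#' respondents with the row syndrome who also meet the column syndrome.
#'
#' @param object An `mhq_crosstab`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mhq_crosstab <- function(object, ...) {
  df <- tidy(object) |>
    mutate(
      row_syndrome = factor(.data$row_syndrome, levels = object$syndromes),
      col_syndrome = factor(.data$col_syndrome, levels = object$syndromes)
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$col_syndrome, .data$row_syndrome,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$pct), "-",
                                                   sprintf("%.0f", .data$pct))),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 100), na.value = "grey90") +
    ggplot2::labs(x = "also meets", y = "respondents with",
                  fill = "row %") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of syndrome prevalence in a phenotyped cohort
#'
#' Percentage meeting each syndrome among respondents assessable on it.
#'
#' @param object An `mhq_phenotypes` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mhq_phenotypes <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    syndrome = c(SYNDROMES, "bipolar"),
    pct = unlist(g[paste0("pct_", c(SYNDROMES, "bipolar"))])
  )
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$syndrome, .data$pct),
                                   .data$pct)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% meeting criteria (assessable respondents)") +
    ggplot2::theme_minimal()
}

#' Faceted view of a characteristics-by-stratum table
#'
#' @param object An `mhq_strattable` from [characteristics_by_stratum()]
#'   or [stratify_by_sex()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mhq_strattable <- function(object, ...) {
  if ("characteristic" %in% names(object)) {
    df <- object |> filter(.data$statistic == "pct")
    ggplot2::ggplot(df, ggplot2::aes(.data$stratum, .data$value)) +
      ggplot2::geom_col(fill = "#2166ac") +
      ggplot2::facet_wrap(~characteristic, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "%") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$syndrome, .data$pct,
                                         fill = .data$stratum)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = NULL, y = "% meeting criteria", fill = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  }
}

#' Bar chart of the five mood-disorder groups
#'
#' @param phenotypes An `mhq_phenotypes` tibble.
#' @return A ggplot; respondents with undefined mood group are shown as
#'   their own bar.
#' @export
plot_mood_groups <- function(phenotypes) {
  df <- phenotypes |>
    mutate(group = forcats_na(.data$mood_group)) |>
    count(.data$group)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "respondents") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

forcats_na <- function(f) {
  x <- as.character(f)
  x[is.na(x)] <- "(undefined)"
  factor(x, levels = c(MOOD_GROUPS, "(undefined)"))
}
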