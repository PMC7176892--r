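# Independent brute-force evaluations of the written case definitions, used
# to check the classifiers over exhaustively enumerated response patterns.
# These are deliberately separate encodings: they reason about screening and
# skipping explicitly from the instrument's branching flow, item by item,
# rather than reusing the package's presented-set machinery.

# depression: full assignment over
# (mood, anh, sym_anh, 6 symptoms, most_day, dur, impair, episodes).
# Branching: anh screen asked only when mood == 0; detail asked unless the
# respondent screened out (mood == 0 and anh == 0).
oracle_depression <- function(g, min_sym = 5L, min_weeks = 2L, rec_min = 2L) {
  mood <- g[, "dep_screen_mood"]
  anh_screen <- ifelse(mood == 1, 0L, g[, "dep_screen_anh"])  # skipped -> not endorsed
  detail <- mood == 1 | anh_screen == 1
  val <- function(col) ifelse(detail, g[, col], 0L)
  anh_any <- anh_screen == 1 | val("dep_sym_anh") == 1
  count <- (mood == 1) + anh_any +
    (val("dep_sym_tired") == 1) + (val("dep_sym_appetite") == 1) +
    (val("dep_sym_sleep") == 1) + (val("dep_sym_conc") == 1) +
    (val("dep_sym_worth") == 1) + (val("dep_sym_death") == 1)
  met <- (mood == 1 | anh_any) &
    val("dep_most_day") == 1 & val("dep_dur_weeks") >= min_weeks &
    count >= min_sym & val("dep_impair") == 1
  cls <- ifelse(met, ifelse(val("dep_episodes") >= rec_min, 2L, 1L), 0L)
  cls
}

oracle_mania <- function(g, min_sym = 3L, min_days = 7L) {
  ela <- g[, "man_screen_elated"]
  irr <- ifelse(ela == 1, 0L, g[, "man_screen_irrit"])
  detail <- ela == 1 | irr == 1
  val <- function(col) ifelse(detail, g[, col], 0L)
  count <- (val("man_sym_active") == 1) + (val("man_sym_talk") == 1) +
    (val("man_sym_sleep") == 1) + (val("man_sym_ideas") == 1)
  as.integer(detail & count >= min_sym & val("man_dur_days") >= min_days)
}

oracle_gad <- function(g, min_sym = 3L, min_months = 6L) {
  scr <- g[, "gad_screen"]
  val <- function(col) ifelse(scr == 1, g[, col], 0L)
  count <- (val("gad_sym_restless") == 1) + (val("gad_sym_keyed") == 1) +
    (val("gad_sym_tired") == 1) + (val("gad_sym_irrit") == 1) +
    (val("gad_sym_sleep") == 1) + (val("gad_sym_conc") == 1)
  as.integer(scr == 1 & val("gad_dur_months") >= min_months &
               val("gad_excess") == 1 & val("gad_control") == 1 &
               count >= min_sym)
}

oracle_audit <- function(g, cutoff = 8L) {
  drinks <- g[, "audit_1"] > 0
  total <- g[, "audit_1"]
  for (k in 2:10) {
    total <- total + ifelse(drinks, g[, sprintf("audit_%d", k)], 0L)
  }
  as.integer(total >= cutoff)
}

oracle_pcl <- function(g, cutoff = 14L) {
  as.integer(rowSums(g[, sprintf("pcl_%d", 1:6), drop = FALSE]) >= cutoff)
}

oracle_ue <- function(g) {
  as.integer(rowSums(g[, c("ue_vision", "ue_voice", "ue_conspiracy",
                           "ue_signal"), drop = FALSE] == 1) >= 1)
}

oracle_cts <- function(g, cutoffs = rep(3L, 5)) {
  hit <- mapply(function(k, cut) g[, sprintf("cts_%d", k)] >= cut, 1:5, cutoffs)
  if (nrow(g) == 1L) hit <- matrix(hit, nrow = 1L)
  as.integer(rowSums(hit) >= 1)
}

# enumerate the full assignment grid over the enumeration domains of the
# given items
full_grid <- function(spec, items) {
  domains <- lapply(items, function(id) {
    spec$items$domain[[match(id, spec$items$item_id)]]
  })
  g <- as.matrix(expand.grid(domains, KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- items
  storage.mode(g) <- "integer"
  g
}

grid_to_responses <- function(g) {
  out <- tibble::as_tibble(as.data.frame(g))
  dplyr::bind_cols(
    tibble::tibble(respondent_id = sprintf("P%d", seq_len(nrow(g)))), out
  )
}
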