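# Synthetic cohort generation. Latent syndrome states follow a
# pairwise-tilted multivariate Bernoulli (an Ising model over the eight
# syndrome indicators: joint mass proportional to
# exp(sum_i alpha_i x_i + sum_{i<j} beta_ij x_i x_j)), with the alpha
# calibrated so realized marginals match the configured prevalences under
# the chosen pairwise tilts. Responses are emitted in two stages per scored
# construct: first a classification-consistency coin (sensitivity for true
# positives, specificity for true negatives), then a concrete response
# pattern drawn uniformly from the enumerated set of patterns whose
# classification under the skip rules equals that outcome. Censoring
# (voluntary refusal, mid-questionnaire abandonment) is applied last.

default_association <- function() {
  B <- matrix(0, 8, 8, dimnames = list(SYNDROMES, SYNDROMES))
  set_tilt <- function(a, b, v) {
    B[a, b] <<- v
    B[b, a] <<- v
  }
  # log odds-ratio tilts reflecting the qualitative comorbidity pattern:
  # anxiety, self-harm, mania and current PTSD cluster strongly with
  # depression (about three-quarters of anxiety cases also meet depression
  # criteria); PTSD raises everything; hazardous drinking adds little.
  set_tilt("depression", "gad", 2.3)
  set_tilt("depression", "self_harm", 1.9)
  set_tilt("depression", "mania", 1.6)
  set_tilt("depression", "ptsd", 1.7)
  set_tilt("depression", "unusual_experiences", 1.0)
  set_tilt("depression", "addiction", 1.1)
  set_tilt("depression", "alcohol", 0.2)
  set_tilt("gad", "ptsd", 1.5)
  set_tilt("gad", "self_harm", 1.0)
  set_tilt("mania", "unusual_experiences", 1.2)
  set_tilt("mania", "self_harm", 1.0)
  set_tilt("ptsd", "unusual_experiences", 1.2)
  set_tilt("ptsd", "self_harm", 1.2)
  set_tilt("ptsd", "addiction", 1.0)
  set_tilt("self_harm", "addiction", 1.0)
  set_tilt("addiction", "alcohol", 1.2)
  set_tilt("alcohol", "mania", 0.3)
  B
}

default_covariate_model <- function() {
  list(
    # binary covariates: P(covariate | states) = plogis(qlogis(base) +
    # sum of offsets over the respondent's positive syndromes)
    sex_male = list(base = 0.43, offsets = c(depression = -0.5, gad = -0.4,
                                             alcohol = 0.6, addiction = 0.5)),
    age_over_cut = list(base = 0.53, offsets = c(
      depression = -0.4, mania = -0.4, gad = -0.4, unusual_experiences = -0.4,
      self_harm = -0.4, alcohol = -0.4, ptsd = -0.4, addiction = -0.4
    )),
    degree = list(base = 0.45, offsets = c(depression = -0.1, addiction = -0.3)),
    renter = list(base = 0.10, offsets = c(depression = 0.4, mania = 0.7,
                                           addiction = 0.9)),
    longstanding_illness = list(base = 0.28, offsets = c(
      depression = 0.5, gad = 0.4, ptsd = 0.5
    )),
    childhood_adversity = list(base = 0.18, offsets = c(
      depression = 0.7, ptsd = 0.9, self_harm = 0.8, mania = 0.4
    )),
    adult_adversity = list(base = 0.25, offsets = c(
      depression = 0.7, ptsd = 0.8, gad = 0.5
    )),
    loneliness = list(base = 0.15, offsets = c(depression = 0.8, gad = 0.5)),
    trauma_exposure = list(base = 0.30, offsets = c(ptsd = 1.5,
                                                    depression = 0.3)),
    # neuroticism: Binomial(12, plogis(qlogis(base) + offsets))
    neuroticism = list(base = 0.35, offsets = c(depression = 0.8, gad = 0.9,
                                                ptsd = 0.5)),
    # Townsend quintile: categorical with base probabilities tilted toward
    # deprivation by exp(tilt * (q - 3)) per positive syndrome
    townsend = list(base = c(0.25, 0.22, 0.20, 0.18, 0.15),
                    tilts = c(addiction = 0.25, mania = 0.20,
                              depression = 0.08)),
    age_min = 45L, age_max = 82L, age_cut = 65L
  )
}

default_behaviour_model <- function() {
  list(
    smoked = list(base = 0.40, offsets = c(depression = 0.4, alcohol = 0.5,
                                           addiction = 0.8)),
    cannabis = list(base = 0.20, offsets = c(depression = 0.4, alcohol = 0.4,
                                             addiction = 1.0)),
    activity = list(base = 0.60, offsets = c()),
    live_alone = list(base = 0.18, lonely_offset = 0.8),
    visit_infrequent = list(base = 0.15, lonely_offset = 0.8),
    group_activity = list(base = 0.55, lonely_offset = -0.7)
  )
}

default_dx_model <- function() {
  # tick probabilities for the professional-diagnosis item, conditional on
  # the relevant latent state
  list(
    depression = list(p_true = 0.55, p_false = 0.10),
    anxiety_nerves = list(p_true = 0.45, p_false = 0.06),
    bipolar = list(p_true = 0.35, p_false = 0.005),
    psychosis = list(p_true = 0.25, p_false = 0.004),
    eating_disorder = list(p_true = 0.015, p_false = 0.015),
    other = list(p_true = 0.10, p_false = 0.03)
  )
}

# constructs emitted by the two-stage scheme, with the latent column driving
# each
CONSTRUCT_TRUTH <- c(
  depression = "depression", mania = "mania", gad = "gad",
  unusual_experiences = "unusual_experiences", self_harm = "self_harm",
  alcohol = "alcohol", ptsd = "ptsd", addiction = "addiction",
  childhood_trauma = "childhood_adversity",
  adult_adversity = "adult_adversity",
  trauma_exposure = "trauma_exposure", loneliness = "loneliness"
)

#' Configure a synthetic cohort
#'
#' Defaults encode the study conditions the package is validated against:
#' marginal prevalences of 24% lifetime depression, 21% past-year
#' hazardous/harmful alcohol use, 7% generalised anxiety, 6% current PTSD,
#' 6% self-reported addiction, 5% unusual experiences, 4% self-harm and 2%
#' hypomania/mania; positive pairwise comorbidity tilts; covariates for a
#' cohort of middle-aged and older adults (ages 45-82 with 53% aged 65 or
#' over, 57% female) whose syndrome-covariate directions follow the
#' published pattern (depression and anxiety more common in women, alcohol
#' and addiction in men, all syndromes rarer over 65, deprivation markers
#' raised with addiction and mania).
#'
#' @param n Number of respondents.
#' @param seed Integer seed; identical config and seed give byte-identical
#'   output.
#' @param marginal_prevalence Named probabilities per syndrome.
#' @param latent_association Symmetric zero-diagonal matrix of pairwise
#'   log-odds tilts over the eight syndromes.
#' @param recurrent_share Probability that a latent depression case is
#'   recurrent rather than single-episode.
#' @param covariate_model,behaviour_model,dx_model Distribution settings;
#'   see `default_covariate_model()` and friends.
#' @param emission_fidelity List with `sensitivity` and `specificity`,
#'   either scalars applied to every construct or named vectors per
#'   construct.
#' @param decline_rate Probability an eligible item is refused.
#' @param partial_rate Probability a respondent abandons mid-questionnaire.
#' @return An `mhq_cohort_config`.
#' @export
cohort_config <- function(n = 1000L, seed = 1L,
                          marginal_prevalence = NULL,
                          latent_association = NULL,
                          recurrent_share = 0.6,
                          covariate_model = NULL,
                          behaviour_model = NULL,
                          dx_model = NULL,
                          emission_fidelity = list(sensitivity = 0.9,
                                                   specificity = 0.97),
                          decline_rate = 0.01,
                          partial_rate = 0.03) {
  prev <- c(
    depression = 0.24, alcohol = 0.21, gad = 0.07, ptsd = 0.06,
    unusual_experiences = 0.05, self_harm = 0.04, mania = 0.02,
    addiction = 0.06
  )
  if (!is.null(marginal_prevalence)) {
    prev[names(marginal_prevalence)] <- marginal_prevalence
  }
  prev <- prev[SYNDROMES]
  if (any(prev < 0 | prev > 1)) abort("marginal prevalences must be in [0, 1]")
  B <- latent_association %||% default_association()
  if (!isTRUE(all.equal(B, t(B))) || any(diag(B) != 0)) {
    abort("latent_association must be symmetric with zero diagonal")
  }
  stopifnot(decline_rate >= 0, decline_rate <= 1,
            partial_rate >= 0, partial_rate <= 1,
            recurrent_share >= 0, recurrent_share <= 1)
  structure(
    list(
      n = as.integer(n), seed = if (!is.null(seed)) as.integer(seed),
      marginal_prevalence = prev,
      latent_association = B,
      recurrent_share = recurrent_share,
      covariate_model = covariate_model %||% default_covariate_model(),
      behaviour_model = behaviour_model %||% default_behaviour_model(),
      dx_model = dx_model %||% default_dx_model(),
      emission_fidelity = emission_fidelity,
      decline_rate = decline_rate,
      partial_rate = partial_rate
    ),
    class = "mhq_cohort_config"
  )
}

#' @export
print.mhq_cohort_config <- function(x, ...) {
  cat(sprintf(
    "<mhq_cohort_config: n=%d seed=%s decline=%.3f partial=%.3f>\n",
    x$n, x$seed %||% "none", x$decline_rate, x$partial_rate
  ))
  invisible(x)
}

fidelity_for <- function(config, construct) {
  f <- config$emission_fidelity
  pick <- function(v) {
    if (length(v) == 1L && is.null(names(v))) return(v)
    if (!is.null(names(v)) && construct %in% names(v)) return(v[[construct]])
    if (!is.null(v[["default"]])) return(v[["default"]])
    v[[1L]]
  }
  se <- pick(f$sensitivity)
  sp <- pick(f$specificity)
  if (se <= 0 || se > 1 || sp <= 0 || sp > 1) {
    abort(sprintf("fidelity for '%s' must lie in (0, 1]", construct))
  }
  c(sensitivity = se, specificity = sp)
}

ising_states <- function() {
  S <- as.matrix(expand.grid(rep(list(0:1), length(SYNDROMES))))
  dimnames(S) <- list(NULL, SYNDROMES)
  storage.mode(S) <- "double"
  S
}

# Calibrate the per-node fields alpha so the model marginals equal `prev`
# under pairwise tilts B, by iterated logit matching over the exact
# enumeration of the 2^8 joint states.
calibrate_ising <- function(prev, B, tol = 1e-10, maxit = 500L) {
  if (any(prev <= 0 | prev >= 1)) {
    abort(paste(
      "calibration infeasible: marginal prevalences must lie strictly",
      "inside (0, 1) (set a syndrome's tilts and prevalence via the",
      "configuration instead of pinning it to 0 or 1)"
    ))
  }
  S <- ising_states()
  q <- 0.5 * rowSums((S %*% B) * S)
  alpha <- qlogis(prev)
  marg <- function(a) {
    w <- exp(as.vector(S %*% a) + q)
    w <- w / sum(w)
    list(w = w, p = as.vector(crossprod(S, w)))
  }
  cur <- marg(alpha)
  err <- max(abs(cur$p - prev))
  for (it in seq_len(maxit)) {
    if (err < tol) return(list(alpha = alpha, prob = cur$w, states = S))
    # Newton step: the Jacobian of the marginals in alpha is the covariance
    # of the state indicators under the current distribution
    ESS <- crossprod(S, S * cur$w)
    J <- ESS - tcrossprod(cur$p)
    step <- tryCatch(solve(J, prev - cur$p),
                     error = function(e) qlogis(prev) - qlogis(cur$p))
    lambda <- 1
    repeat {
      cand <- marg(alpha + lambda * step)
      cand_err <- max(abs(cand$p - prev))
      if (cand_err < err || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (cand_err >= err && lambda < 1e-6) break
    alpha <- alpha + lambda * step
    cur <- cand
    err <- cand_err
  }
  if (err < tol) return(list(alpha = alpha, prob = cur$w, states = S))
  abort("calibration infeasible: marginals did not converge under the given tilts")
}

logistic_given_states <- function(X, model) {
  eta <- rep(qlogis(model$base), nrow(X))
  off <- model$offsets
  if (length(off) > 0L) {
    eta <- eta + as.vector(X[, names(off), drop = FALSE] %*% off)
  }
  plogis(eta)
}

#' Sample latent respondent profiles
#'
#' Draws syndrome indicators from the calibrated pairwise-tilted
#' multivariate Bernoulli and covariates conditional on them, returning the
#' simulation ground truth.
#'
#' @param config An `mhq_cohort_config`.
#' @param seed Seed (defaults to the config's); `NULL` continues the
#'   current RNG stream.
#' @return An `mhq_latent` tibble, one row per respondent.
#' @export
sample_latent <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  cal <- calibrate_ising(config$marginal_prevalence, config$latent_association)
  if (n == 0L) {
    idx <- integer()
  } else {
    idx <- sample.int(nrow(cal$states), n, replace = TRUE, prob = cal$prob)
  }
  X <- cal$states[idx, , drop = FALSE]
  cm <- config$covariate_model
  draw <- function(model) runif(n) < logistic_given_states(X, model)

  recurrent <- X[, "depression"] == 1 & runif(n) < config$recurrent_share
  over_cut <- draw(cm$age_over_cut)
  age <- ifelse(
    over_cut,
    sample(seq.int(cm$age_cut, cm$age_max), n, replace = TRUE),
    sample(seq.int(cm$age_min, cm$age_cut - 1L), n, replace = TRUE)
  )
  tilt <- cm$townsend$tilts
  t_eta <- if (length(tilt) > 0L) {
    as.vector(X[, names(tilt), drop = FALSE] %*% tilt)
  } else {
    rep(0, n)
  }
  if (n > 0L) {
    tw_probs <- outer(t_eta, 1:5, function(e, q) e * (q - 3)) |>
      (\(m) exp(m) * rep(cm$townsend$base, each = n))()
    tw_probs <- tw_probs / rowSums(tw_probs)
    townsend <- 1L + rowSums(runif(n) > t(apply(tw_probs, 1, cumsum)))
  } else {
    townsend <- integer()
  }

  neuro_p <- plogis(qlogis(cm$neuroticism$base) +
                      as.vector(X[, names(cm$neuroticism$offsets),
                                  drop = FALSE] %*% cm$neuroticism$offsets))

  out <- tibble(
    respondent_id = sprintf("R%07d", seq_len(n)),
    depression = X[, "depression"] == 1,
    depression_single = X[, "depression"] == 1 & !recurrent,
    depression_recurrent = recurrent,
    mania = X[, "mania"] == 1,
    gad = X[, "gad"] == 1,
    unusual_experiences = X[, "unusual_experiences"] == 1,
    self_harm = X[, "self_harm"] == 1,
    alcohol = X[, "alcohol"] == 1,
    ptsd = X[, "ptsd"] == 1,
    addiction = X[, "addiction"] == 1,
    age_years = as.integer(age),
    sex = factor(ifelse(draw(cm$sex_male), "male", "female"),
                 levels = c("female", "male")),
    degree_holder = draw(cm$degree),
    townsend_quintile = as.integer(townsend),
    renter = draw(cm$renter),
    longstanding_illness = draw(cm$longstanding_illness),
    neuroticism_score = rbinom(n, 12L, neuro_p),
    childhood_adversity = draw(cm$childhood_adversity),
    adult_adversity = draw(cm$adult_adversity),
    trauma_exposure = draw(cm$trauma_exposure),
    loneliness = draw(cm$loneliness)
  )
  structure(out, class = c("mhq_latent", class(out)))
}

# ---------------------------------------------------------------------------
# pattern enumeration: for each construct, every full assignment over the
# bound items' enumeration domains, classified once under the skip rules;
# emission then samples uniformly within a classification class. Assignments
# retain values for rule-skipped items ("shadow" values): they are not
# written to the record unless censoring of a trigger re-exposes the block.

construct_items <- function(ruleset, construct) {
  b <- ruleset[[construct]]
  switch(construct,
    depression = c(b$screen_mood, b$screen_anh, b$symptom_anh,
                   b$symptom_items, b$most_day, b$duration, b$impairment,
                   b$episodes),
    mania = c(b$screen_elated, b$screen_irritable, b$symptom_items,
              b$duration),
    gad = c(b$screen, b$duration, b$excessive, b$control, b$symptom_items),
    unusual_experiences = b$items,
    self_harm = b$item,
    alcohol = b$items,
    ptsd = b$items,
    addiction = b$item,
    childhood_trauma = b$items,
    adult_adversity = b$items,
    trauma_exposure = b$items,
    loneliness = c(b$lonely, b$confide),
    abort(sprintf("unknown construct '%s'", construct))
  )
}

# classification of a grid of assignments, as integer class labels:
# 0 = not met, 1 = met (for depression: 1 = met single, 2 = met recurrent)
classify_grid <- function(construct, grid, spec, ruleset) {
  fake <- as_tibble(as.data.frame(grid))
  fake <- bind_cols(tibble(respondent_id = sprintf("P%d", seq_len(nrow(grid)))),
                    fake)
  if (construct == "depression") {
    res <- classify_depression(fake, spec, ruleset)
    rec_min <- ruleset$depression$recurrent_min_episodes
    cls <- ifelse(res$status == "met",
                  ifelse(!is.na(res$episode_count) &
                           res$episode_count >= rec_min, 2L, 1L), 0L)
  } else {
    res <- switch(construct,
      mania = classify_mania(fake, spec, ruleset),
      gad = classify_gad(fake, spec, ruleset),
      unusual_experiences = classify_unusual_experiences(fake, spec, ruleset),
      self_harm = classify_self_harm(fake, spec, ruleset),
      alcohol = classify_alcohol(fake, spec, ruleset),
      ptsd = classify_ptsd(fake, spec, ruleset),
      addiction = classify_addiction(fake, spec, ruleset),
      childhood_trauma = tibble(status = tri_from_grid_ct(fake, ruleset)),
      adult_adversity = tibble(status = tv_status(
        tv_any(as.matrix(fake[, ruleset$adult_adversity$items]) == 1)
      )),
      trauma_exposure = tibble(status = tv_status(tv_count_ge(
        as.matrix(fake[, ruleset$trauma_exposure$items]) == 1,
        ruleset$trauma_exposure$min_count
      ))),
      loneliness = tibble(status = tv_status(tv_count_ge(
        cbind(fake[[ruleset$loneliness$lonely]] == 1,
              fake[[ruleset$loneliness$confide]] <=
                ruleset$loneliness$confide_max),
        ruleset$loneliness$min_score
      )))
    )
    if (any(res$status == "unassessable")) {
      abort(sprintf(
        "internal consistency error: construct '%s' has unclassifiable patterns",
        construct
      ))
    }
    cls <- as.integer(res$status == "met")
  }
  cls
}

tri_from_grid_ct <- function(fake, ruleset) {
  b <- ruleset$childhood_trauma
  ind <- mapply(function(item, cut) fake[[item]] >= cut, b$items,
                b$item_cutoffs)
  if (nrow(fake) == 1L) ind <- matrix(ind, nrow = 1L)
  tv_status(tv_any(ind))
}

.pattern_cache <- new.env(parent = emptyenv())

pattern_cache <- function(spec, ruleset) {
  key <- rlang::hash(list(spec, unclass(ruleset)))
  if (!is.null(.pattern_cache[[key]])) return(.pattern_cache[[key]])
  cache <- lapply(names(CONSTRUCT_TRUTH), function(construct) {
    items <- construct_items(ruleset, construct)
    missing_items <- setdiff(items, spec$items$item_id)
    if (length(missing_items) > 0L) {
      abort(sprintf(
        "ruleset binds item(s) absent from the instrument: %s",
        paste(missing_items, collapse = ", ")
      ))
    }
    domains <- lapply(items, function(id) item_domain(spec, id))
    grid <- as.matrix(expand.grid(domains, KEEP.OUT.ATTRS = FALSE))
    colnames(grid) <- items
    storage.mode(grid) <- "integer"
    cls <- classify_grid(construct, grid, spec, ruleset)
    rows <- split(seq_len(nrow(grid)), cls)
    needed <- if (construct == "depression") c("0", "1", "2") else c("0", "1")
    if (!all(needed %in% names(rows))) {
      abort(sprintf(
        "internal consistency error: construct '%s' has no pattern for class %s",
        construct, paste(setdiff(needed, names(rows)), collapse = ", ")
      ))
    }
    list(items = items, grid = grid, rows = rows)
  })
  names(cache) <- names(CONSTRUCT_TRUTH)
  .pattern_cache[[key]] <- cache
  cache
}

#' Emit skip-consistent responses for latent profiles
#'
#' Two-stage emission per scored construct: a classification-consistency
#' coin (sensitivity / specificity), then a uniform draw from the response
#' patterns consistent with that outcome under the instrument's skip rules.
#' Voluntary refusal and mid-questionnaire abandonment are applied
#' afterwards. Every emitted record passes [validate_responses()] with zero
#' violations.
#'
#' @param profiles An `mhq_latent` tibble from [sample_latent()].
#' @param spec An `mhq_instrument`.
#' @param config An `mhq_cohort_config`.
#' @param ruleset A `mhq_ruleset`.
#' @param seed Seed; `NULL` (default) continues the current RNG stream so
#'   [generate_cohort()] governs reproducibility with a single seed.
#' @return A wide response tibble.
#' @export
emit_responses <- function(profiles, spec = default_instrument(),
                           config = cohort_config(n = nrow(profiles)),
                           ruleset = default_ruleset(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(profiles)
  cache <- pattern_cache(spec, ruleset)
  ids <- spec$items$item_id
  V <- matrix(NA_integer_, nrow = n, ncol = length(ids),
              dimnames = list(NULL, ids))
  dx_col <- rep("0", n)

  # -- two-stage constructs ----------------------------------------------
  for (construct in names(CONSTRUCT_TRUTH)) {
    fid <- fidelity_for(config, construct)
    truth <- profiles[[CONSTRUCT_TRUTH[[construct]]]]
    if (construct == "depression") {
      true_cls <- ifelse(profiles$depression_recurrent, 2L,
                         ifelse(profiles$depression_single, 1L, 0L))
      keep <- runif(n) < fid[["sensitivity"]]
      false_pos <- runif(n) < 1 - fid[["specificity"]]
      fp_cls <- ifelse(runif(n) < config$recurrent_share, 2L, 1L)
      obs <- ifelse(true_cls > 0L, ifelse(keep, true_cls, 0L),
                    ifelse(false_pos, fp_cls, 0L))
    } else {
      obs <- ifelse(truth,
                    as.integer(runif(n) < fid[["sensitivity"]]),
                    as.integer(runif(n) < 1 - fid[["specificity"]]))
    }
    cc <- cache[[construct]]
    pick <- integer(n)
    for (cls in unique(obs)) {
      rows <- cc$rows[[as.character(cls)]]
      sel <- which(obs == cls)
      pick[sel] <- rows[sample.int(length(rows), length(sel), replace = TRUE)]
    }
    if (n > 0L) V[, cc$items] <- cc$grid[pick, , drop = FALSE]
  }

  # -- demographics and behaviours ---------------------------------------
  X <- sapply(SYNDROMES, function(s) as.numeric(profiles[[s]]))
  if (n == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, SYNDROMES))
  if (n == 0L) X <- matrix(0, nrow = 0L, ncol = length(SYNDROMES),
                           dimnames = list(NULL, SYNDROMES))
  bm <- config$behaviour_model
  dm <- ruleset$demographics
  V[, dm$age] <- profiles$age_years
  V[, dm$sex] <- as.integer(profiles$sex == "male")
  V[, dm$degree] <- as.integer(profiles$degree_holder)
  V[, dm$townsend] <- profiles$townsend_quintile
  V[, dm$tenure] <- ifelse(
    profiles$renter,
    sample(c(3L, 4L), n, replace = TRUE),
    sample(c(1L, 2L, 5L), n, replace = TRUE, prob = c(0.55, 0.35, 0.10))
  )
  V[, dm$illness] <- as.integer(profiles$longstanding_illness)
  V[, dm$neuroticism] <- profiles$neuroticism_score
  V[, dm$smoked] <- as.integer(runif(n) < logistic_given_states(X, bm$smoked))
  V[, dm$cannabis] <- as.integer(runif(n) <
                                   logistic_given_states(X, bm$cannabis))
  V[, dm$activity] <- as.integer(runif(n) <
                                   logistic_given_states(X, bm$activity))
  lonely <- as.numeric(profiles$loneliness)
  bump <- function(model) plogis(qlogis(model$base) + model$lonely_offset * lonely)
  si <- ruleset$social_isolation
  V[, si$live_alone] <- as.integer(runif(n) < bump(bm$live_alone))
  infreq <- runif(n) < bump(bm$visit_infrequent)
  V[, si$visits] <- ifelse(infreq, sample(4:5, n, replace = TRUE),
                           sample(1:3, n, replace = TRUE))
  V[, si$group] <- as.integer(runif(n) < bump(bm$group_activity))

  # -- self-reported diagnoses -------------------------------------------
  dxm <- config$dx_model
  conds <- list(
    depression = profiles$depression,
    anxiety_nerves = profiles$gad,
    bipolar = profiles$depression & profiles$mania,
    psychosis = profiles$unusual_experiences,
    eating_disorder = rep(FALSE, n),
    other = profiles$addiction
  )
  cats <- ruleset$diagnoses$categories
  ticks <- sapply(names(cats), function(cat) {
    p <- ifelse(conds[[cat]], dxm[[cat]]$p_true, dxm[[cat]]$p_false)
    runif(n) < p
  })
  if (n == 1L) ticks <- matrix(ticks, nrow = 1L, dimnames = list(NULL, names(cats)))
  if (n > 0L) {
    dx_col <- apply(ticks, 1, function(t) {
      if (!any(t)) "0" else paste(cats[names(cats)[t]], collapse = ";")
    })
  }

  # -- censoring and skip-consistent assembly ----------------------------
  K <- length(ids)
  declined <- matrix(runif(n * K) < config$decline_rate, nrow = n, ncol = K,
                     dimnames = list(NULL, ids))
  is_partial <- runif(n) < config$partial_rate
  cut_at <- sample(2:K, n, replace = TRUE)
  cut <- outer(seq_len(n), seq_len(K),
               function(i, j) is_partial[i] & j >= cut_at[i])
  colnames(cut) <- ids

  pres <- matrix(TRUE, nrow = n, ncol = K, dimnames = list(NULL, ids))
  if (length(spec$rules) > 0L && n > 0L) {
    ord <- order(rule_trigger_positions(spec))
    for (r in spec$rules[ord]) {
      tr <- r$trigger_item
      fired <- pres[, tr] & !declined[, tr] & !cut[, tr] &
        V[, tr] %in% r$trigger_codes
      if (any(fired)) pres[fired, r$skipped_items] <- FALSE
    }
  }

  out <- tibble(respondent_id = profiles$respondent_id)
  for (id in ids) {
    if (id == ruleset$diagnoses$item) {
      x <- dx_col
      x[pres[, id] & cut[, id]] <- NA_character_
      x[pres[, id] & !cut[, id] & declined[, id]] <- "-818"
      x[!pres[, id]] <- NA_character_
    } else {
      x <- V[, id]
      x[pres[, id] & cut[, id]] <- NA_integer_
      x[pres[, id] & !cut[, id] & declined[, id]] <- CODE_DECLINED
      x[!pres[, id]] <- NA_integer_
    }
    out[[id]] <- x
  }
  out
}

#' Generate a synthetic cohort with ground truth
#'
#' Pairs [sample_latent()] with [emit_responses()] under the config's
#' single seed. The truth table carries one latent profile per emitted
#' record, supporting parameter-recovery and fidelity tests downstream.
#'
#' @inheritParams emit_responses
#' @param config An `mhq_cohort_config`.
#' @param spec An `mhq_instrument`.
#' @return An `mhq_cohort`: a list with `responses` (wide tibble), `truth`
#'   (`mhq_latent`) and the `config` used.
#' @export
generate_cohort <- function(config = cohort_config(),
                            spec = default_instrument(),
                            ruleset = default_ruleset()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- sample_latent(config, seed = NULL)
  responses <- emit_responses(truth, spec, config, ruleset, seed = NULL)
  structure(
    list(responses = responses, truth = truth, config = config),
    class = "mhq_cohort"
  )
}

#' @export
print.mhq_cohort <- function(x, ...) {
  cat(sprintf("<mhq_cohort: %d respondents, %d items>\n",
              nrow(x$responses), ncol(x$responses) - 1L))
  invisible(x)
}
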