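# Synthetic corpora with known ground truth, emulating the reporting
# heterogeneity of the published DDM literature: per-article scaling
# conventions (s = 0.1 vs 1), mixed RT units (including T_er-only
# milliseconds), absolute vs relative starting point, response-coded drift,
# individual vs aggregated reporting, parameters constrained across
# conditions, and multiplicative outlier contamination.

#' Reference prior specifications for the canonical DDM parameters
#'
#' The dominant-component prior for each canonical parameter kind, as fitted
#' to the pooled literature: a zero-truncated normal for `v` (location 1.76,
#' scale 1.51), a gamma for `a` (shape 11.69, scale 0.12), truncated
#' Student-t distributions for `T_er` (0.44, 0.08, df 1.32), mirrored `z_r`
#' (0.5, 0.05, df 1.85) and `s_T_er` (0.17, 0.04, df 0.88), a
#' zero-truncated normal for `s_v` (1.36, 0.69), and a truncated normal on
#' `[0, 1]` for `s_z_r` (0.33, 0.22). These serve as the generator's default
#' ground-truth distributions.
#'
#' @return Named list of [dist_spec()] objects, one per canonical kind.
#' @export
default_true_priors <- function() {
  list(
    v = dist_spec("truncated_normal", c(location = 1.76, scale = 1.51)),
    a = dist_spec("gamma", c(shape = 11.69, scale = 0.12)),
    z_r = dist_spec("truncated_t", c(location = 0.5, scale = 0.05, df = 1.85),
                    lower = 0, upper = 1),
    T_er = dist_spec("truncated_t", c(location = 0.44, scale = 0.08, df = 1.32)),
    s_v = dist_spec("truncated_normal", c(location = 1.36, scale = 0.69)),
    s_z_r = dist_spec("truncated_normal", c(location = 0.33, scale = 0.22),
                      lower = 0, upper = 1),
    s_T_er = dist_spec("truncated_t", c(location = 0.17, scale = 0.04, df = 0.88))
  )
}

#' Configuration of the synthetic-corpus generator
#'
#' @param n_articles Number of articles (one study each).
#' @param conditions_per_study Integer range (length-2 vector) of conditions.
#' @param participants_per_study Integer range of participants, used by
#'   individually-reporting articles.
#' @param true_priors Named list of [dist_spec()]/[mixture_spec()] ground
#'   truths per canonical kind; defaults to [default_true_priors()].
#' @param fraction_s01 Proportion of articles scaled to `s = 0.1`.
#' @param fraction_ms Proportion reporting every time-dependent parameter in
#'   milliseconds.
#' @param fraction_ter_ms_only Proportion reporting only `T_er`/`s_T_er` in
#'   milliseconds (the mixed-unit dialect), drawn from the non-`fraction_ms`
#'   remainder.
#' @param fraction_individual Proportion reporting individual estimates.
#' @param fraction_absolute_z Proportion reporting absolute `z`/`s_z` rather
#'   than `z_r`/`s_z_r`.
#' @param fraction_response_coded Proportion reporting response-coded
#'   (signed) drift rates.
#' @param constrained_kinds Kinds held constant across a study's conditions.
#' @param outlier_rate Per-row multiplicative contamination probability.
#' @param outlier_scale Contamination multiplier.
#' @param seed Integer seed; a fixed seed makes the corpus byte-identical.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_articles = 100,
                             conditions_per_study = c(2L, 4L),
                             participants_per_study = c(10L, 30L),
                             true_priors = default_true_priors(),
                             fraction_s01 = 0.4,
                             fraction_ms = 0.1,
                             fraction_ter_ms_only = 0.15,
                             fraction_individual = 0.05,
                             fraction_absolute_z = 0.3,
                             fraction_response_coded = 0.2,
                             constrained_kinds = c("T_er", "s_v", "s_z_r", "s_T_er"),
                             outlier_rate = 0.02,
                             outlier_scale = 3,
                             seed = 1L) {
  props <- c(fraction_s01, fraction_ms, fraction_ter_ms_only,
             fraction_individual, fraction_absolute_z, fraction_response_coded,
             outlier_rate)
  if (any(props < 0 | props > 1)) {
    stop("config error: proportions must lie in [0, 1]", call. = FALSE)
  }
  if (fraction_ms + fraction_ter_ms_only > 1) {
    stop("config error: fraction_ms + fraction_ter_ms_only must not exceed 1",
         call. = FALSE)
  }
  stopifnot(n_articles >= 0, length(conditions_per_study) == 2,
            conditions_per_study[1] >= 1,
            conditions_per_study[2] >= conditions_per_study[1],
            length(participants_per_study) == 2,
            participants_per_study[1] >= 1,
            participants_per_study[2] >= participants_per_study[1],
            outlier_scale > 0)
  missing_kinds <- setdiff(.canonical_kinds, names(true_priors))
  if (length(missing_kinds)) {
    stop("config error: true_priors missing kind(s): ",
         paste(missing_kinds, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(constrained_kinds, .canonical_kinds)
  if (length(bad)) stop("config error: unknown constrained kind(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    n_articles = as.integer(n_articles),
    conditions_per_study = as.integer(conditions_per_study),
    participants_per_study = as.integer(participants_per_study),
    true_priors = true_priors,
    fraction_s01 = fraction_s01, fraction_ms = fraction_ms,
    fraction_ter_ms_only = fraction_ter_ms_only,
    fraction_individual = fraction_individual,
    fraction_absolute_z = fraction_absolute_z,
    fraction_response_coded = fraction_response_coded,
    constrained_kinds = constrained_kinds,
    outlier_rate = outlier_rate, outlier_scale = outlier_scale,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# draw one integer from an inclusive range (sample() treats a scalar as 1:n)
.sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
}

.task_tags <- c("lexical decision", "random dot motion", "recognition memory",
                "numerosity", "brightness discrimination")
.population_tags <- c("non-clinical", "clinical", "older adults")

#' Generate a synthetic corpus with known ground truth
#'
#' Draws canonical-scale (`s = 1`, seconds, relative starting point,
#' accuracy-coded) parameter values per article/condition (per participant
#' for individually-reporting articles) from the configured true priors,
#' then applies the inverse of the canonicalization per article according to
#' its sampled reporting conventions: re-scaling to `s = 0.1`, conversion to
#' milliseconds (optionally only for `T_er`/`s_T_er`), absolute starting
#' point `z = z_r * a`, signed response-coded drift, replication of
#' constrained kinds across conditions, and multiplicative outliers.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a [ddm_corpus()]), `ground_truth` (data frame
#'   of canonical condition-level values keyed by article/study/condition/
#'   kind, with `outlier` flags), and `conventions` (per-article sampled
#'   reporting conventions).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  rows <- list(); truth <- list(); conv <- list()

  for (i in seq_len(config$n_articles)) {
    art <- sprintf("art%03d", i)
    study <- "s1"
    n_cond <- .sample_range(config$conditions_per_study)
    individual <- stats::runif(1) < config$fraction_individual
    n_part <- if (individual) .sample_range(config$participants_per_study) else 1L
    s_rep <- if (stats::runif(1) < config$fraction_s01) 0.1 else 1
    u <- stats::runif(1)
    unit_mode <- if (u < config$fraction_ms) "all_ms" else
      if (u < config$fraction_ms + config$fraction_ter_ms_only) "ter_ms" else
        "seconds"
    absolute_z <- stats::runif(1) < config$fraction_absolute_z
    response_coded <- stats::runif(1) < config$fraction_response_coded
    explicit_s <- stats::runif(1) < 0.5
    software <- if (explicit_s) sample(c("other", "unknown"), 1) else
      if (s_rep == 0.1) "DMAT" else sample(c("HDDM", "fastDM"), 1)
    task <- sample(.task_tags, 1)
    population <- sample(.population_tags, 1)
    conv[[i]] <- data.frame(
      article_id = art, s_reported = s_rep, unit_mode = unit_mode,
      individual = individual, absolute_z = absolute_z,
      response_coded = response_coded, software = software,
      n_conditions = n_cond, n_participants = n_part,
      task = task, population = population, stringsAsFactors = FALSE)

    for (kind in .canonical_kinds) {
      constrained <- kind %in% config$constrained_kinds
      n_free_cond <- if (constrained) 1L else n_cond
      # canonical draws: one per free condition slot per participant
      draws <- matrix(sample_spec(config$true_priors[[kind]],
                                  n_free_cond * n_part),
                      nrow = n_part, ncol = n_free_cond)
      cond_truth <- colMeans(draws)

      for (ci in seq_len(n_cond)) {
        slot <- if (constrained) 1L else ci
        group <- if (constrained) paste0(kind, "_all") else
          sprintf("%s_c%d", kind, ci)
        for (p in seq_len(n_part)) {
          canonical <- draws[p, slot]
          value <- canonical
          out_kind <- kind

          # response coding: signed drift with arbitrary boundary assignment
          if (kind == "v" && response_coded && stats::runif(1) < 0.5) {
            value <- -value
          }
          # absolute starting point: z = z_r * a of the same condition
          if (kind %in% c("z_r", "s_z_r") && absolute_z) {
            a_slot <- if ("a" %in% config$constrained_kinds) 1L else ci
            # note: uses the same participant's a draw when individual
            a_val <- get("a_draws", envir = art_env)[p, a_slot]
            value <- value * a_val
            out_kind <- if (kind == "z_r") "z" else "s_z"
          }
          # inverse re-scaling to the article's s
          if (.kind_class(out_kind) == "accumulation") value <- value * s_rep
          # inverse seconds conversion
          ms_here <- unit_mode == "all_ms" ||
            (unit_mode == "ter_ms" && out_kind %in% c("T_er", "s_T_er"))
          if (ms_here) {
            if (.kind_class(out_kind) == "time") value <- value * 1000
            if (out_kind %in% c("v", "s_v")) value <- value / sqrt(1000)
            if (out_kind %in% c("a", "z", "s_z")) value <- value * sqrt(1000)
          }
          outlier <- stats::runif(1) < config$outlier_rate
          if (outlier) value <- value * config$outlier_scale

          rows[[length(rows) + 1L]] <- data.frame(
            article_id = art, study_id = study,
            condition_id = sprintf("c%d", ci),
            participant_id = if (individual) sprintf("p%02d", p) else NA_character_,
            kind = out_kind, value = value,
            s_reported = if (explicit_s) s_rep else NA_real_,
            software = software, rt_unit = "unknown",
            reporting_level = if (individual) "individual" else "aggregated",
            constraint_group = group,
            n_participants = n_part,
            task = task, population = population,
            stringsAsFactors = FALSE)
          if (outlier) {
            attr(rows[[length(rows)]], "outlier") <- TRUE
          }
        }
        truth[[length(truth) + 1L]] <- data.frame(
          article_id = art, study_id = study,
          condition_id = sprintf("c%d", ci), kind = kind,
          canonical_value = cond_truth[slot],
          constrained = constrained,
          stringsAsFactors = FALSE)
      }
      if (kind == "a") {
        # stash the a draws so absolute-z articles can reconstruct z = z_r * a
        art_env <- new.env()
        assign("a_draws", draws, envir = art_env)
      }
    }
  }

  estimates <- if (length(rows)) do.call(rbind, rows) else
    .empty_estimates()
  outlier_flag <- if (length(rows)) {
    vapply(rows, function(r) isTRUE(attr(r, "outlier")), logical(1))
  } else logical(0)

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(article_id = character(), study_id = character(),
               condition_id = character(), kind = character(),
               canonical_value = numeric(), constrained = logical(),
               stringsAsFactors = FALSE)
  conv_df <- if (length(conv)) do.call(rbind, conv) else
    data.frame(article_id = character(), stringsAsFactors = FALSE)

  # mark conditions touched by an outlier row
  if (nrow(truth_df)) {
    key_est <- paste(estimates$article_id, estimates$study_id,
                     estimates$condition_id,
                     ifelse(estimates$kind == "z", "z_r",
                            ifelse(estimates$kind == "s_z", "s_z_r",
                                   estimates$kind)), sep = "\r")
    out_keys <- unique(key_est[outlier_flag])
    # constrained kinds replicate one value: an outlier row contaminates only
    # the replicate it sits on, but dedup may keep it, so mark the whole group
    key_truth <- paste(truth_df$article_id, truth_df$study_id,
                       truth_df$condition_id, truth_df$kind, sep = "\r")
    truth_df$outlier <- key_truth %in% out_keys
    grp_key_est <- paste(estimates$article_id, estimates$study_id,
                         ifelse(estimates$kind == "z", "z_r",
                                ifelse(estimates$kind == "s_z", "s_z_r",
                                       estimates$kind)), sep = "\r")
    grp_out <- unique(grp_key_est[outlier_flag &
                                    grepl("_all$", estimates$constraint_group)])
    grp_key_truth <- paste(truth_df$article_id, truth_df$study_id,
                           truth_df$kind, sep = "\r")
    truth_df$outlier <- truth_df$outlier |
      (truth_df$constrained & grp_key_truth %in% grp_out)
  }

  corpus <- ddm_corpus(estimates,
                       provenance = list(source = "synthetic generator",
                                         seed = config$seed))
  list(corpus = corpus, ground_truth = truth_df, conventions = conv_df)
}

.empty_estimates <- function() {
  data.frame(article_id = character(), study_id = character(),
             condition_id = character(), participant_id = character(),
             kind = character(), value = numeric(), s_reported = numeric(),
             software = character(), rt_unit = character(),
             reporting_level = character(), constraint_group = character(),
             n_participants = integer(), task = character(),
             population = character(), stringsAsFactors = FALSE)
}

#' Generator/pipeline round-trip consistency check
#'
#' Generates a corpus, runs the full canonicalization pipeline, and compares
#' the recovered canonical values against the generator's ground truth.
#' With `outlier_rate = 0` and successful unit inference the maximum
#' absolute discrepancy is expected to be numerically zero (below 1e-9).
#'
#' @param config A [generator_config()].
#' @return List with `max_discrepancy`, `n_compared`, `per_kind` (named
#'   vector of per-kind maxima), `unit_mismatches` (articles whose inferred
#'   unit mode disagrees with the generating convention), and
#'   `n_articles`.
#' @export
round_trip_check <- function(config) {
  gen <- generate_corpus(config)
  if (nrow(gen$corpus$estimates) == 0) {
    return(list(max_discrepancy = NA_real_, n_compared = 0L,
                per_kind = numeric(0), unit_mismatches = character(0),
                n_articles = 0L))
  }
  canon <- canonicalize_corpus(gen$corpus)
  df <- canon$corpus$estimates
  key_est <- paste(df$article_id, df$study_id, df$condition_id, df$kind,
                   sep = "\r")
  tr <- gen$ground_truth
  key_truth <- paste(tr$article_id, tr$study_id, tr$condition_id, tr$kind,
                     sep = "\r")
  m <- match(key_est, key_truth)
  ok <- !is.na(m) & !tr$outlier[m]
  diffs <- abs(df$value[ok] - tr$canonical_value[m[ok]])
  per_kind <- tapply(diffs, df$kind[ok], max)

  # unit-inference audit against the generating conventions
  mism <- character(0)
  units <- canon$units
  for (art in unique(gen$conventions$article_id)) {
    cv <- gen$conventions[gen$conventions$article_id == art, ]
    ua <- units[units$article_id == art, ]
    exp_ter <- if (cv$unit_mode %in% c("all_ms", "ter_ms")) "milliseconds" else "seconds"
    exp_rest <- if (cv$unit_mode == "all_ms") "milliseconds" else "seconds"
    got_ter <- ua$unit[ua$kind == "T_er"]
    got_rest <- ua$unit[ua$kind %in% c("v", "a", "z", "s_v", "s_z")][1]
    if ((length(got_ter) && !is.na(got_ter) && got_ter != exp_ter) ||
        (length(got_rest) && !is.na(got_rest) && got_rest != exp_rest)) {
      mism <- c(mism, art)
    }
  }
  list(max_discrepancy = if (length(diffs)) max(diffs) else NA_real_,
       n_compared = sum(ok),
       per_kind = per_kind,
       unit_mismatches = mism,
       n_articles = config$n_articles)
}
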