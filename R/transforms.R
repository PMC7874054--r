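# Canonicalization: every estimate is brought to the s = 1, seconds scale,
# with relative starting point, accuracy-coded drift, constrained parameters
# deduplicated and individual estimates averaged, in a fixed stage order:
#   resolve s -> infer RT units -> convert to seconds -> rescale to s = 1 ->
#   z, s_z -> z_r, s_z_r -> accuracy-code v -> plausibility screen ->
#   deduplicate constrained -> average individuals -> (mirror z_r at pooling)

#' Resolve the scaling parameter of each estimate
#'
#' Published fits are scaled relative to a fixed moment-to-moment drift
#' variability `s` (typically 0.1 or 1), which multiplies every
#' accumulation-scaled parameter. Resolution order: an explicit `s_reported`
#' value; otherwise the estimation software's default (DMAT fixes `s = 0.1`;
#' HDDM and fast-DM fix `s = 1`); otherwise an author-specific rule supplied
#' via `author_rules`. Rows still unknown after all three are destined for
#' exclusion (with a logged count) because their scale cannot be recovered.
#'
#' @param corpus A [ddm_corpus()].
#' @param author_rules Optional data frame with columns `article_id` and `s`,
#'   assigning a known scaling convention to specific articles (e.g. labs
#'   known to fix `s = 0.1`).
#' @return The corpus with `s_reported` filled where resolvable; the integer
#'   attribute `"n_unresolved"` counts rows that remain unknown.
#' @export
resolve_scaling <- function(corpus, author_rules = NULL) {
  stopifnot(inherits(corpus, "ddm_corpus"))
  df <- corpus$estimates
  s <- df$s_reported
  sw_default <- c(DMAT = 0.1, HDDM = 1, fastDM = 1)
  idx <- is.na(s) & df$software %in% names(sw_default)
  s[idx] <- sw_default[df$software[idx]]
  if (!is.null(author_rules)) {
    m <- match(df$article_id, author_rules$article_id)
    idx <- is.na(s) & !is.na(m)
    s[idx] <- author_rules$s[m[idx]]
  }
  corpus$estimates$s_reported <- s
  attr(corpus, "n_unresolved") <- sum(is.na(s))
  corpus
}

#' Re-scale estimates to a common scaling parameter
#'
#' Multiplies every accumulation-scaled estimate (`v`, `a`, `z`, `s_v`,
#' `s_z`) by `s_target / s_reported`; time-only (`T_er`, `s_T_er`) and
#' dimensionless (`z_r`, `s_z_r`) kinds are untouched. After the operation
#' all rows carry `s_reported = s_target`.
#'
#' @param corpus A [ddm_corpus()] whose `s_reported` is fully resolved.
#' @param s_target Target scaling parameter (default 1).
#' @return The re-scaled corpus.
#' @export
rescale_to_unit_s <- function(corpus, s_target = 1) {
  stopifnot(inherits(corpus, "ddm_corpus"), s_target > 0)
  df <- corpus$estimates
  if (any(is.na(df$s_reported))) {
    stop("unresolvable scale: s_reported unknown for ",
         sum(is.na(df$s_reported)), " row(s); resolve or exclude them first",
         call. = FALSE)
  }
  acc <- .kind_class(df$kind) == "accumulation"
  df$value[acc] <- df$value[acc] * (s_target / df$s_reported[acc])
  df$s_reported <- s_target
  corpus$estimates <- df
  corpus
}

#' Rough expected decision time
#'
#' `E(RT) = (a - z) / v`: the mean time for a noiseless accumulator starting
#' at `z` to drift to the upper boundary `a` at rate `v`. Used as a
#' magnitude plausibility screen to infer the reporting time unit of
#' published estimates.
#'
#' @param a Boundary separation (> 0).
#' @param z Starting point, `0 <= z <= a`.
#' @param v Drift rate (non-zero).
#' @return `(a - z) / v`, in the same time unit as the inputs.
#' @examples
#' expected_rt(a = 0.12, z = 0.06, v = 0.25)  # 0.24
#' @export
expected_rt <- function(a, z, v) {
  if (any(v == 0)) stop("undefined expectation: v = 0", call. = FALSE)
  if (any(a <= 0)) stop("domain error: a must be > 0", call. = FALSE)
  if (any(z > a | z < 0)) stop("domain error: z must lie in [0, a]", call. = FALSE)
  (a - z) / v
}

#' Infer the reporting time unit of an article's estimates
#'
#' Articles rarely state whether estimates are on the seconds or milliseconds
#' scale, and sometimes mix the two (e.g. `T_er` in milliseconds, the rest in
#' seconds). The two-step magnitude rule:
#' \enumerate{
#'   \item `T_er` (and `s_T_er`) are in seconds iff the reported `T_er` is
#'     smaller than 5, otherwise milliseconds (median over the article's
#'     `T_er` rows when several are present).
#'   \item the remaining parameters are in seconds iff the rough expected
#'     decision time `E(RT) = (a - z)/v` is smaller than 10, otherwise
#'     milliseconds; the minimum `E(RT)` over the article's conditions is
#'     used (the most conservative choice against misclassifying slow-RT
#'     designs), with `z` derived as `z_r * a` when only bias is reported.
#' }
#' When a step cannot run (no `T_er` row; no complete `(a, z, v)` triple) the
#' step is flagged unresolved and the pipeline falls back to the declared
#' `rt_unit` or the software default (seconds).
#'
#' @param article_estimates Data frame of one article's estimate rows (the
#'   `estimates` slot of a corpus subset), on the reported scale.
#' @return Data frame with one row per parameter kind present, columns
#'   `kind`, `unit` (`"seconds"`, `"milliseconds"`, or `NA` when unresolved;
#'   dimensionless kinds get `"none"`), and `basis` (`"ter_rule"`,
#'   `"ert_rule"`, `"dimensionless"`, or `"unresolved"`). Attributes
#'   `step1_resolved` and `step2_resolved` report whether each step ran.
#' @export
infer_rt_units <- function(article_estimates) {
  df <- article_estimates
  if (inherits(df, "ddm_corpus")) df <- df$estimates

  ter_vals <- df$value[df$kind == "T_er"]
  step1 <- length(ter_vals) > 0
  unit_ter <- if (step1) {
    if (stats::median(ter_vals) < 5) "seconds" else "milliseconds"
  } else NA_character_

  # assemble per-condition (a, z, v) triples on the reported scale
  erts <- c()
  conds <- unique(df[, c("study_id", "condition_id")])
  for (i in seq_len(nrow(conds))) {
    sub <- df[df$study_id == conds$study_id[i] &
                df$condition_id == conds$condition_id[i], , drop = FALSE]
    a <- mean(abs(sub$value[sub$kind == "a"]))
    v <- mean(abs(sub$value[sub$kind == "v"]))
    if (any(sub$kind == "z")) {
      z <- mean(abs(sub$value[sub$kind == "z"]))
    } else if (any(sub$kind == "z_r") && is.finite(a)) {
      z <- mean(sub$value[sub$kind == "z_r"]) * a
    } else {
      z <- NaN
    }
    if (is.finite(a) && is.finite(v) && is.finite(z) &&
        v > 0 && a > 0 && z >= 0 && z <= a) {
      erts <- c(erts, expected_rt(a, z, v))
    }
  }
  step2 <- length(erts) > 0
  unit_rest <- if (step2) {
    if (min(erts) < 10) "seconds" else "milliseconds"
  } else NA_character_

  kinds <- unique(df$kind)
  unit <- vapply(kinds, function(k) {
    switch(.kind_class(k),
           time = unit_ter,
           accumulation = unit_rest,
           dimensionless = "none")
  }, character(1))
  basis <- vapply(kinds, function(k) {
    switch(.kind_class(k),
           time = if (step1) "ter_rule" else "unresolved",
           accumulation = if (step2) "ert_rule" else "unresolved",
           dimensionless = "dimensionless")
  }, character(1))
  out <- data.frame(kind = kinds, unit = unname(unit), basis = unname(basis),
                    stringsAsFactors = FALSE)
  attr(out, "step1_resolved") <- step1
  attr(out, "step2_resolved") <- step2
  out
}

#' Convert estimates to the seconds scale
#'
#' Rows assigned the milliseconds unit are converted with time ratio `k`
#' (1000 ms per s). Plain times divide by `k`. Accumulation-scaled kinds
#' follow the diffusion scaling law with the diffusion coefficient `s` held
#' fixed: rescaling time by `1/k` multiplies drift-like quantities (`v`,
#' `s_v`) by `sqrt(k)` and divides evidence-like quantities (`a`, `z`,
#' `s_z`) by `sqrt(k)`, the unique linear transformation that preserves the
#' first-passage process. Dimensionless kinds are unchanged. A consistency
#' guarantee follows: `E(RT)` computed after conversion equals `E(RT)`
#' before conversion divided by `k`.
#'
#' @param corpus A [ddm_corpus()].
#' @param units Character vector, one entry per corpus row (recycled if
#'   length 1): `"seconds"` (identity), `"milliseconds"`, or `"none"`.
#' @param k Time-unit ratio (default 1000).
#' @return The converted corpus; converted rows have `rt_unit` set to
#'   `"seconds"`.
#' @export
convert_to_seconds <- function(corpus, units, k = 1000) {
  stopifnot(inherits(corpus, "ddm_corpus"), k > 0)
  df <- corpus$estimates
  units <- rep_len(units, nrow(df))
  if (any(is.na(units))) {
    stop("unresolved unit for ", sum(is.na(units)), " row(s)", call. = FALSE)
  }
  bad <- !(units %in% c("seconds", "milliseconds", "none"))
  if (any(bad)) stop("invalid unit value(s): ",
                     paste(unique(units[bad]), collapse = ", "), call. = FALSE)
  ms <- units == "milliseconds"
  cls <- .kind_class(df$kind)
  i <- ms & cls == "time"
  df$value[i] <- df$value[i] / k
  i <- ms & df$kind %in% c("v", "s_v")
  df$value[i] <- df$value[i] * sqrt(k)
  i <- ms & df$kind %in% c("a", "z", "s_z")
  df$value[i] <- df$value[i] / sqrt(k)
  df$rt_unit[ms | units == "seconds"] <- "seconds"
  corpus$estimates <- df
  corpus
}

#' Relative starting point
#'
#' Maps the absolute starting point `z` (or its across-trial range `s_z`) to
#' the bias scale: `z_r = z / a`, in `[0, 1]`, where `z_r = 0.5` indicates
#' unbiased responding.
#'
#' @param z Absolute starting point (or `s_z`), `0 <= z <= a`.
#' @param a Boundary separation, `> 0`.
#' @return `z / a`.
#' @examples
#' to_relative_start(z = 0.06, a = 0.12)  # 0.5
#' @export
to_relative_start <- function(z, a) {
  if (any(a <= 0)) stop("domain error: a must be > 0", call. = FALSE)
  if (any(z < 0 | z > a)) {
    stop("domain error: z must lie in [0, a]", call. = FALSE)
  }
  z / a
}

#' Mirror a sample of bias estimates
#'
#' The attribution of response options to the two boundaries is arbitrary,
#' so the direction of bias cannot be made commensurate across articles.
#' Pooling therefore uses both `x` and `1 - x` for every reported bias,
#' producing a "mirrored" distribution that is symmetric with mean exactly
#' 0.5 while retaining the variability information. Applies to `z_r` only.
#'
#' @param values Numeric vector of bias values in `[0, 1]`.
#' @return Numeric vector of length `2 * length(values)`: the input followed
#'   by its reflection about 0.5.
#' @examples
#' mirror_bias(c(0.4, 0.55))  # 0.40 0.55 0.60 0.45
#' @export
mirror_bias <- function(values) {
  if (length(values) == 0) return(numeric(0))
  if (any(values < 0 | values > 1)) {
    stop("domain error: bias values must lie in [0, 1]", call. = FALSE)
  }
  c(values, 1 - values)
}

#' Accuracy-code drift rates
#'
#' Under accuracy coding a positive drift rate means evidence toward the
#' correct response; articles using response coding report signed drifts
#' whose sign reflects an arbitrary boundary assignment. Pooling uses the
#' absolute values.
#'
#' @param values Numeric vector of reported drift rates.
#' @return `abs(values)`, order preserved.
#' @export
accuracy_code_drift <- function(values) abs(values)

#' Deduplicate parameters constrained across conditions
#'
#' A parameter held fixed across an article's conditions is one free
#' parameter, however many condition rows repeat it; only one representative
#' per (article, study, participant, kind, constraint group) is retained —
#' the first after a deterministic sort on (article_id, study_id,
#' condition_id), so the result does not depend on file row order.
#'
#' @param corpus A [ddm_corpus()] (or its `estimates` data frame).
#' @return Object of the same type with duplicates removed; the integer
#'   attribute `"n_removed"` counts dropped rows.
#' @export
deduplicate_constrained <- function(corpus) {
  df <- if (inherits(corpus, "ddm_corpus")) corpus$estimates else corpus
  ord <- order(df$article_id, df$study_id, df$condition_id)
  df <- df[ord, , drop = FALSE]
  pid <- ifelse(is.na(df$participant_id), "", df$participant_id)
  key <- paste(df$article_id, df$study_id, pid, df$kind, df$constraint_group,
               sep = "\r")
  keep <- !duplicated(key)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (inherits(corpus, "ddm_corpus")) {
    corpus$estimates <- out
    attr(corpus, "n_removed") <- sum(!keep)
    corpus
  } else {
    attr(out, "n_removed") <- sum(!keep)
    out
  }
}

#' Average individual estimates within studies
#'
#' Studies reporting per-participant estimates contribute, per study and
#' condition, the arithmetic mean across participants, so that every pooled
#' row carries equal weight across studies regardless of reporting level.
#' Aggregated and group-level rows pass through untouched.
#'
#' @param corpus A [ddm_corpus()] (or its `estimates` data frame).
#' @return Object of the same type; averaged rows are relabeled
#'   `reporting_level = "aggregated"` with `n_participants` set to the group
#'   size. The integer attribute `"n_groups_averaged"` counts collapsed
#'   groups.
#' @export
average_individuals <- function(corpus) {
  df <- if (inherits(corpus, "ddm_corpus")) corpus$estimates else corpus
  ind <- !is.na(df$reporting_level) & df$reporting_level == "individual"
  n_groups <- 0L
  if (any(ind)) {
    sub <- df[ind, , drop = FALSE]
    key <- paste(sub$article_id, sub$study_id, sub$condition_id, sub$kind,
                 sep = "\r")
    first <- !duplicated(key)
    means <- tapply(sub$value, key, mean)
    sizes <- tapply(sub$value, key, length)
    agg <- sub[first, , drop = FALSE]
    k <- paste(agg$article_id, agg$study_id, agg$condition_id, agg$kind,
               sep = "\r")
    agg$value <- as.numeric(means[k])
    agg$n_participants <- as.integer(sizes[k])
    agg$participant_id <- NA_character_
    agg$reporting_level <- "aggregated"
    n_groups <- nrow(agg)
    df <- rbind(df[!ind, , drop = FALSE], agg)
    df <- df[order(df$article_id, df$study_id, df$condition_id, df$kind), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  if (inherits(corpus, "ddm_corpus")) {
    corpus$estimates <- df
    attr(corpus, "n_groups_averaged") <- n_groups
    corpus
  } else {
    attr(df, "n_groups_averaged") <- n_groups
    df
  }
}

#' Pool canonicalized estimates for one parameter kind
#'
#' Collects the canonical values of one parameter kind across all articles
#' and conditions into a single univariate sample, optionally restricted by
#' task and/or population tag. For `z_r` the values are mirrored (see
#' [mirror_bias()]), which doubles the sample. Empirical bounds are the
#' sample extrema.
#'
#' @param corpus A canonicalized [ddm_corpus()] or the result of
#'   [canonicalize_corpus()].
#' @param kind One of the canonical kinds `v`, `a`, `z_r`, `T_er`, `s_v`,
#'   `s_z_r`, `s_T_er`.
#' @param task,population Optional tag filters (exact equality).
#' @return A `pooled_sample`: list with `kind`, `values`, `n` (pooled count,
#'   post-mirroring for `z_r`), `n_source` (pre-mirroring count),
#'   `empirical_lower`, `empirical_upper`.
#' @export
pool_estimates <- function(corpus, kind, task = NULL, population = NULL) {
  if (inherits(corpus, "ddm_canonical")) corpus <- corpus$corpus
  stopifnot(inherits(corpus, "ddm_corpus"))
  kind <- match.arg(kind, .canonical_kinds)
  df <- corpus$estimates
  if (!is.null(task)) df <- df[!is.na(df$task) & df$task == task, , drop = FALSE]
  if (!is.null(population)) {
    df <- df[!is.na(df$population) & df$population == population, , drop = FALSE]
  }
  values <- df$value[df$kind == kind]
  if (length(values) == 0) {
    stop("empty sample: no '", kind, "' estimates after filtering", call. = FALSE)
  }
  n_source <- length(values)
  if (kind == "z_r") values <- mirror_bias(values)
  structure(list(kind = kind, values = values, n = length(values),
                 n_source = n_source,
                 empirical_lower = min(values), empirical_upper = max(values)),
            class = "pooled_sample")
}

#' @export
print.pooled_sample <- function(x, ...) {
  cat(sprintf("<pooled_sample> %s: n = %d (source rows %d), range [%.4g, %.4g]\n",
              x$kind, x$n, x$n_source, x$empirical_lower, x$empirical_upper))
  invisible(x)
}

#' Run the full canonicalization pipeline
#'
#' Applies, in the canonical order, every transform needed to make reported
#' estimates comparable across articles: scale resolution, per-article RT
#' unit inference with fallback to declared/software units,
#' millisecond-to-second conversion, re-scaling to `s = 1`, conversion of
#' absolute starting quantities to the bias scale, accuracy coding of drift,
#' the plausibility screen (with logged exclusion), deduplication of
#' constrained parameters, and averaging of individual estimates. Mirroring
#' of `z_r` happens later, at pooling.
#'
#' Every exclusion is logged, never silent: rows with unresolvable `s`, `z`
#' or `s_z` rows with no matching `a`, and (optionally) rows flagged
#' implausible are removed with per-stage counts in the audit.
#'
#' @param corpus A raw [ddm_corpus()].
#' @param author_rules Passed to [resolve_scaling()].
#' @param k Time-unit ratio for [convert_to_seconds()].
#' @param exclude_implausible Drop rows flagged by [validate_plausibility()]
#'   (default `TRUE`).
#' @param s_target Target scaling parameter (default 1).
#' @return An object of class `ddm_canonical`: list with `corpus` (the
#'   canonical [ddm_corpus()], whose estimates carry a `transform_log`
#'   column), `audit` (per-stage data frame of `n_in`, `n_excluded`,
#'   `n_out`), `exclusions` (row-level exclusion log), `flags` (plausibility
#'   flags), and `units` (per-article unit assignment).
#' @export
canonicalize_corpus <- function(corpus, author_rules = NULL, k = 1000,
                                exclude_implausible = TRUE, s_target = 1) {
  stopifnot(inherits(corpus, "ddm_corpus"))
  audit <- list()
  exclusions <- list()
  note <- function(stage, n_in, n_excluded) {
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = stage, n_in = n_in, n_excluded = n_excluded,
      n_out = n_in - n_excluded, stringsAsFactors = FALSE)
  }
  drop_rows <- function(df, idx, reason) {
    if (length(idx)) {
      exclusions[[length(exclusions) + 1L]] <<- data.frame(
        article_id = df$article_id[idx], study_id = df$study_id[idx],
        kind = df$kind[idx], value = df$value[idx], reason = reason,
        stringsAsFactors = FALSE)
      df <- df[-idx, , drop = FALSE]
      rownames(df) <- NULL
    }
    df
  }

  df <- corpus$estimates
  df$transform_log <- ""
  log_stage <- function(df, rows, stage) {
    df$transform_log[rows] <- ifelse(df$transform_log[rows] == "", stage,
                                     paste(df$transform_log[rows], stage,
                                           sep = ";"))
    df
  }
  note("read", nrow(df), 0L)

  # --- resolve scaling parameter -----------------------------------------
  corpus$estimates <- df
  corpus <- resolve_scaling(corpus, author_rules)
  df <- corpus$estimates
  unres <- which(is.na(df$s_reported))
  note("resolve_s", nrow(df), length(unres))
  df <- drop_rows(df, unres, "unknown scaling parameter s")
  df <- log_stage(df, seq_len(nrow(df)), "resolve_s")

  # --- infer RT units per article, fall back to declared/software unit ---
  unit_rows <- rep(NA_character_, nrow(df))
  unit_log <- list()
  for (art in unique(df$article_id)) {
    rows <- which(df$article_id == art)
    inf <- infer_rt_units(df[rows, , drop = FALSE])
    u <- inf$unit[match(df$kind[rows], inf$kind)]
    # fallback: declared unit, else software default (seconds)
    fb <- ifelse(df$rt_unit[rows] %in% c("seconds", "milliseconds"),
                 df$rt_unit[rows], "seconds")
    u[is.na(u)] <- fb[is.na(u)]
    unit_rows[rows] <- u
    unit_log[[art]] <- cbind(article_id = art, inf)
  }
  units <- do.call(rbind, unit_log)
  rownames(units) <- NULL
  note("infer_rt_units", nrow(df), 0L)
  df <- log_stage(df, seq_len(nrow(df)), "infer_rt_units")

  # --- convert to seconds -------------------------------------------------
  corpus$estimates <- df
  corpus <- convert_to_seconds(corpus, unit_rows, k = k)
  df <- log_stage(corpus$estimates, which(unit_rows == "milliseconds"),
                  "convert_to_seconds")
  note("convert_to_seconds", nrow(df), 0L)

  # --- rescale to s = s_target -------------------------------------------
  corpus$estimates <- df
  corpus <- rescale_to_unit_s(corpus, s_target = s_target)
  df <- log_stage(corpus$estimates,
                  which(.kind_class(corpus$estimates$kind) == "accumulation"),
                  "rescale_to_unit_s")
  note("rescale_to_unit_s", nrow(df), 0L)

  # --- absolute z, s_z -> relative z_r, s_z_r ----------------------------
  abs_rows <- which(df$kind %in% c("z", "s_z"))
  unmatched <- integer(0)
  if (length(abs_rows)) {
    pid <- ifelse(is.na(df$participant_id), "", df$participant_id)
    a_rows <- df$kind == "a"
    for (i in abs_rows) {
      same <- a_rows & df$article_id == df$article_id[i] &
        df$study_id == df$study_id[i] & df$condition_id == df$condition_id[i]
      exact <- same & pid == pid[i]
      a_val <- if (any(exact)) mean(df$value[exact])
               else if (any(same)) mean(df$value[same]) else NA_real_
      if (is.na(a_val) || a_val <= 0) {
        unmatched <- c(unmatched, i)
      } else {
        df$value[i] <- df$value[i] / a_val
        df$kind[i] <- if (df$kind[i] == "z") "z_r" else "s_z_r"
      }
    }
    df <- log_stage(df, setdiff(abs_rows, unmatched), "to_relative_start")
  }
  note("to_relative_start", nrow(df), length(unmatched))
  df <- drop_rows(df, unmatched, "no matching boundary separation for z/s_z")

  # --- accuracy-code drift ------------------------------------------------
  vr <- which(df$kind == "v")
  df$value[vr] <- accuracy_code_drift(df$value[vr])
  df <- log_stage(df, vr, "accuracy_code_drift")
  note("accuracy_code_drift", nrow(df), 0L)

  # --- plausibility screen ------------------------------------------------
  corpus$estimates <- df
  flags <- validate_plausibility(corpus)
  n_flagged <- length(unique(flags$row[!is.na(flags$row)]))
  if (exclude_implausible && n_flagged > 0) {
    bad <- sort(unique(flags$row[!is.na(flags$row)]))
    note("plausibility_screen", nrow(df), length(bad))
    df <- drop_rows(df, bad, "implausible after canonicalization")
  } else {
    note("plausibility_screen", nrow(df), 0L)
  }
  df <- log_stage(df, seq_len(nrow(df)), "plausibility_screen")

  # --- deduplicate constrained parameters --------------------------------
  df2 <- deduplicate_constrained(df)
  note("deduplicate_constrained", nrow(df), attr(df2, "n_removed"))
  df <- log_stage(df2, seq_len(nrow(df2)), "deduplicate_constrained")

  # --- average individual estimates --------------------------------------
  n_before <- nrow(df)
  df2 <- average_individuals(df)
  note("average_individuals", n_before, n_before - nrow(df2))
  df <- log_stage(df2, seq_len(nrow(df2)), "average_individuals")

  corpus$estimates <- df
  structure(list(
    corpus = corpus,
    audit = do.call(rbind, audit),
    exclusions = if (length(exclusions)) do.call(rbind, exclusions) else
      data.frame(article_id = character(), study_id = character(),
                 kind = character(), value = numeric(), reason = character(),
                 stringsAsFactors = FALSE),
    flags = flags,
    units = units
  ), class = "ddm_canonical")
}

#' @export
print.ddm_canonical <- function(x, ...) {
  cat("<ddm_canonical> canonicalized corpus\n")
  print(x$audit, row.names = FALSE)
  invisible(x)
}
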