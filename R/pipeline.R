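# Orchestration: corpus -> canonicalization -> per-kind candidate fitting ->
# Akaike-weight selection -> dominant-component prior table.

#' Run the full parameter review
#'
#' Canonicalizes a corpus, pools each canonical parameter kind (optionally
#' restricted by task/population tags), fits the kind's candidate set by
#' constrained maximum likelihood, selects the Akaike-weight-best model, and
#' extracts the dominant component as the proposed informative prior.
#' Deterministic given `seed`.
#'
#' Kinds with fewer than `min_n` pooled values are reported as unfit-able
#' rather than fitted (fitting a flexible candidate set to a handful of
#' estimates is not meaningful).
#'
#' @param corpus A [ddm_corpus()] (raw; it is canonicalized internally) or a
#'   `ddm_canonical` result.
#' @param task,population Optional tag filters applied before pooling.
#' @param n_starts Restarts per candidate fit (see [fit_ml()]).
#' @param seed Integer seed controlling all fitting randomness.
#' @param min_n Minimum pooled sample size to attempt fitting (default 10).
#' @param author_rules,k,exclude_implausible Passed to
#'   [canonicalize_corpus()] when `corpus` is raw.
#' @return A `prior_table`: list with `priors` (named list of `prior_spec`
#'   per kind, `NULL` where unfit-able), `table` (Table-style data frame),
#'   `fits` (per-kind candidate comparison tables), `audit`, `exclusions`,
#'   `filters`, `seed`.
#' @export
run_review <- function(corpus, task = NULL, population = NULL, n_starts = 20,
                       seed = 1, min_n = 10, author_rules = NULL, k = 1000,
                       exclude_implausible = TRUE) {
  canon <- if (inherits(corpus, "ddm_canonical")) corpus else
    canonicalize_corpus(corpus, author_rules = author_rules, k = k,
                        exclude_implausible = exclude_implausible)

  priors <- stats::setNames(vector("list", length(.canonical_kinds)),
                            .canonical_kinds)
  fit_tables <- list()
  rows <- list()
  for (kind in .canonical_kinds) {
    sample <- tryCatch(pool_estimates(canon, kind, task = task,
                                      population = population),
                       error = function(e) NULL)
    if (is.null(sample) || sample$n < min_n) {
      rows[[kind]] <- data.frame(
        kind = kind, n = if (is.null(sample)) 0L else sample$n,
        distribution = NA_character_, weight = NA_real_,
        location_shape = NA_real_, scale = NA_real_, df = NA_real_,
        t_lb = .kind_bounds(kind)[1], t_ub = .kind_bounds(kind)[2],
        e_lb = NA_real_, e_ub = NA_real_, waic = NA_real_,
        status = "unfit-able", stringsAsFactors = FALSE)
      next
    }
    cands <- candidate_set(kind)
    fits <- lapply(seq_along(cands), function(i) {
      fit_ml(sample, cands[[i]], n_starts = n_starts, seed = seed + i)
    })
    fits <- akaike_weights(fits)
    best <- select_best(fits)
    prior <- dominant_component(best, sample)
    priors[[kind]] <- prior
    fit_tables[[kind]] <- .fits_table(fits)

    d <- prior$distribution
    rows[[kind]] <- data.frame(
      kind = kind, n = sample$n, distribution = best$label,
      weight = prior$mixture_weight,
      location_shape = unname(d$params[1]), scale = unname(d$params[["scale"]]),
      df = if (d$family == "truncated_t") unname(d$params[["df"]]) else NA_real_,
      t_lb = d$lower, t_ub = d$upper,
      e_lb = sample$empirical_lower, e_ub = sample$empirical_upper,
      waic = best$waic, status = "fitted", stringsAsFactors = FALSE)
  }

  structure(list(
    priors = priors,
    table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    fits = fit_tables,
    audit = canon$audit,
    exclusions = canon$exclusions,
    filters = list(task = task, population = population),
    seed = seed
  ), class = "prior_table")
}

#' @export
print.prior_table <- function(x, ...) {
  cat("<prior_table> informative prior distributions\n")
  tab <- x$table
  tab$weight <- ifelse(is.na(tab$weight), "-", sprintf("%.2f", tab$weight))
  print(tab, row.names = FALSE, digits = 4)
  if (!is.null(x$filters$task) || !is.null(x$filters$population)) {
    cat("filters:",
        if (!is.null(x$filters$task)) paste0("task=", x$filters$task),
        if (!is.null(x$filters$population))
          paste0("population=", x$filters$population), "\n")
  }
  invisible(x)
}

#' Serialize a prior table
#'
#' Writes the prior table to JSON (lossless: full parameter vectors,
#' truncation and empirical bounds, audit counts; [read_priors()] round
#' trips it) or CSV (the tabular summary; single-family rows print an empty
#' weight).
#'
#' @param table A `prior_table` from [run_review()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, `path`.
#' @export
serialize_priors <- function(table, path, format = c("json", "csv")) {
  stopifnot(inherits(table, "prior_table"))
  format <- match.arg(format)
  if (format == "csv") {
    out <- table$table[, c("kind", "n", "distribution", "weight",
                           "location_shape", "scale", "df", "t_lb", "t_ub",
                           "e_lb", "e_ub")]
    out$weight <- ifelse(is.na(out$weight), "", sprintf("%.6g", out$weight))
    utils::write.csv(out, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  ser_spec <- function(d) {
    if (is.null(d)) return(NULL)
    list(family = d$family, params = as.list(d$params),
         lower = d$lower,
         upper = if (is.finite(d$upper)) d$upper else "Inf")
  }
  priors <- lapply(table$priors, function(p) {
    if (is.null(p)) return(NULL)
    list(kind = p$kind, distribution = ser_spec(p$distribution),
         mixture_weight = if (is.na(p$mixture_weight)) NULL else p$mixture_weight,
         waic = p$waic, selected_label = p$selected_label,
         n = p$n, n_source = p$n_source,
         empirical_lower = p$empirical_lower,
         empirical_upper = p$empirical_upper)
  })
  tab <- table$table
  tab$t_ub <- ifelse(is.finite(tab$t_ub), tab$t_ub, "Inf")
  obj <- list(priors = priors, table = tab, audit = table$audit,
              filters = table$filters, seed = table$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON prior table
#'
#' @param path Path written by [serialize_priors()] with `format = "json"`.
#' @return A `prior_table` (fits and exclusions are not serialized and come
#'   back `NULL`).
#' @export
read_priors <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  priors <- lapply(obj$priors, function(p) {
    if (is.null(p)) return(NULL)
    d <- p$distribution
    spec <- dist_spec(d$family, unlist(d$params), lower = d$lower,
                      upper = if (is.null(d$upper) || is.character(d$upper))
                        Inf else d$upper)
    structure(list(
      kind = p$kind, distribution = spec,
      mixture_weight = if (is.null(p$mixture_weight)) NA_real_ else p$mixture_weight,
      waic = p$waic, selected_label = p$selected_label,
      n = p$n, n_source = p$n_source,
      empirical_lower = p$empirical_lower,
      empirical_upper = p$empirical_upper), class = "prior_spec")
  })
  names(priors) <- names(obj$priors)
  tab <- do.call(rbind, lapply(obj$table, function(r) {
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)
  }))
  if (!is.null(tab$t_ub)) {
    tab$t_ub <- suppressWarnings(ifelse(tab$t_ub == "Inf", Inf,
                                        as.numeric(tab$t_ub)))
    tab$t_lb <- as.numeric(tab$t_lb)
  }
  structure(list(priors = priors, table = tab,
                 fits = NULL,
                 audit = do.call(rbind, lapply(obj$audit, as.data.frame)),
                 exclusions = NULL,
                 filters = obj$filters, seed = obj$seed),
            class = "prior_table")
}

#' Draw parameter values from a prior
#'
#' Samples from the truncated prior density; all draws fall inside the
#' truncation bounds.
#'
#' @param prior A `prior_spec` (from [run_review()]/[dominant_component()])
#'   or a bare [dist_spec()]/[mixture_spec()].
#' @param n Number of draws (> 0).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
sample_prior <- function(prior, n, seed = 1) {
  stopifnot(n > 0)
  spec <- if (inherits(prior, "prior_spec")) prior$distribution else prior
  if (!inherits(spec, "dist_spec") && !inherits(spec, "mixture_spec")) {
    stop("spec error: not a distribution specification", call. = FALSE)
  }
  set.seed(seed)
  sample_spec(spec, n)
}

#' Prior-predictive first-passage simulation
#'
#' Simulates the diffusion decision process for each supplied parameter
#' vector by Euler discretization: starting from `z = z_r * a`, Gaussian
#' increments with mean `v * dt` and standard deviation `s * sqrt(dt)`
#' accumulate until crossing 0 or `a`; the response time is the
#' first-passage time plus `T_er`. One trial is simulated per parameter
#' row. A sanity tool for checking that priors imply plausible behavior,
#' not a fitting engine; the discretization bias is of order `dt`.
#'
#' In the noiseless limit (`s -> 0`, `v > 0`) the simulated RT converges to
#' `T_er + (a - z) / v`, the rough expected-RT screening formula.
#'
#' @param draws Data frame (or list) with columns/elements `v`, `a`, `z_r`,
#'   `T_er`, recycled to a common length.
#' @param s Diffusion coefficient (default 1, the canonical scale).
#' @param dt Euler step in seconds (default 1e-4).
#' @param seed Integer seed.
#' @param max_t Simulation horizon per trial in seconds; non-terminated
#'   trials are censored at `max_t` and reported.
#' @return List with `mean_rt`, `accuracy` (fraction absorbed at the upper
#'   boundary), `quantiles` (RT deciles), `rt` and `upper` per trial, and
#'   `n_censored`.
#' @export
prior_predictive_rt <- function(draws, s = 1, dt = 1e-4, seed = 1,
                                max_t = 30) {
  v <- draws$v; a <- draws$a; z_r <- draws$z_r; T_er <- draws$T_er
  n <- max(length(v), length(a), length(z_r), length(T_er))
  v <- rep_len(v, n); a <- rep_len(a, n)
  z_r <- rep_len(z_r, n); T_er <- rep_len(T_er, n)
  if (any(a <= 0)) stop("domain error: a must be > 0", call. = FALSE)
  if (any(z_r <= 0 | z_r >= 1)) {
    stop("domain error: z_r must lie in (0, 1)", call. = FALSE)
  }
  if (any(T_er < 0)) stop("domain error: T_er must be >= 0", call. = FALSE)
  stopifnot(dt > 0, s >= 0)

  set.seed(seed)
  pos <- z_r * a
  active <- rep(TRUE, n)
  t_dec <- numeric(n)
  upper <- rep(NA, n)
  n_steps <- ceiling(max_t / dt)
  sd_step <- s * sqrt(dt)
  step <- 0L
  while (any(active) && step < n_steps) {
    step <- step + 1L
    idx <- which(active)
    pos[idx] <- pos[idx] + v[idx] * dt +
      if (sd_step > 0) stats::rnorm(length(idx), 0, sd_step) else 0
    hit_up <- idx[pos[idx] >= a[idx]]
    hit_lo <- idx[pos[idx] <= 0]
    hit_lo <- setdiff(hit_lo, hit_up)
    done <- c(hit_up, hit_lo)
    if (length(done)) {
      t_dec[done] <- step * dt
      upper[hit_up] <- TRUE
      upper[hit_lo] <- FALSE
      active[done] <- FALSE
    }
  }
  n_censored <- sum(active)
  t_dec[active] <- max_t
  rt <- T_er + t_dec
  list(mean_rt = mean(rt),
       accuracy = mean(upper[!active & !is.na(upper)]),
       quantiles = stats::quantile(rt, probs = seq(0.1, 0.9, by = 0.1)),
       rt = rt, upper = upper, n_censored = n_censored)
}
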