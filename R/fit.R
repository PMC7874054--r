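# Constrained maximum-likelihood fitting of truncated/mixture candidates by
# multi-start local optimization in an unconstrained reparameterization
# (log for positive parameters, logit for the mixture weight).

#' Candidate templates for one parameter kind
#'
#' Enumerates the candidate densities fitted to a pooled sample. For the
#' `[0, 1]`-bounded kinds (`z_r`, `s_z_r`): truncated normal and truncated t
#' on `[0, 1]`, plus the allowed two-component mixtures truncated to
#' `[0, 1]`. For all other kinds: the five single families and the four
#' allowed mixtures on `[0, Inf)` (gamma + gamma, and truncated normal with
#' each of gamma, lognormal, truncated normal). Truncation bounds are fixed
#' constants of the kind, not free parameters.
#'
#' @param kind A canonical parameter kind (see [parameter_kinds()]).
#' @return List of template objects (class `dist_template`), each with
#'   `type` (`"single"`/`"mixture"`), `families`, `lower`, `upper`, `label`.
#' @examples
#' length(candidate_set("a"))    # 9
#' length(candidate_set("z_r"))  # 6
#' @export
candidate_set <- function(kind) {
  kind <- match.arg(kind, .canonical_kinds)
  b <- .kind_bounds(kind)
  singles <- if (identical(b, c(0, 1))) {
    c("truncated_normal", "truncated_t")
  } else {
    .dist_families
  }
  mixtures <- list(c("gamma", "gamma"),
                   c("truncated_normal", "gamma"),
                   c("truncated_normal", "lognormal"),
                   c("truncated_normal", "truncated_normal"))
  out <- lapply(singles, function(f) {
    structure(list(type = "single", families = f, lower = b[1], upper = b[2],
                   label = f), class = "dist_template")
  })
  out <- c(out, lapply(mixtures, function(fs) {
    structure(list(type = "mixture", families = fs, lower = b[1], upper = b[2],
                   label = paste(fs, collapse = "+")), class = "dist_template")
  }))
  out
}

# ---- unconstrained reparameterization -----------------------------------

.par_transform <- function(family) {
  # TRUE where the natural parameter is positive-constrained (log transform)
  switch(family,
         truncated_normal = c(location = FALSE, scale = TRUE),
         lognormal        = c(location = FALSE, scale = TRUE),
         gamma            = c(shape = TRUE, scale = TRUE),
         weibull          = c(shape = TRUE, scale = TRUE),
         truncated_t      = c(location = FALSE, scale = TRUE, df = TRUE))
}

.to_eta <- function(family, params) {
  pos <- .par_transform(family)
  ifelse(pos, log(pmax(params[names(pos)], 1e-12)), params[names(pos)])
}

.from_eta <- function(family, eta) {
  pos <- .par_transform(family)
  p <- ifelse(pos, exp(eta), eta)
  names(p) <- names(pos)
  p
}

.template_n_eta <- function(template) {
  ks <- vapply(template$families, function(f) length(.par_transform(f)), 1L)
  if (template$type == "single") ks else sum(ks) + 1L
}

.spec_from_eta <- function(template, eta) {
  if (template$type == "single") {
    dist_spec(template$families, .from_eta(template$families, eta),
              template$lower, template$upper)
  } else {
    k1 <- length(.par_transform(template$families[1]))
    w <- stats::plogis(eta[1])
    c1 <- dist_spec(template$families[1],
                    .from_eta(template$families[1], eta[2:(1 + k1)]),
                    template$lower, template$upper)
    c2 <- dist_spec(template$families[2],
                    .from_eta(template$families[2], eta[-(1:(1 + k1))]),
                    template$lower, template$upper)
    mixture_spec(w, c1, c2)
  }
}

# structural support check: does any sample point have zero density under
# every admissible parameterization of the template?
.template_supports <- function(template, x) {
  if (any(x < template$lower | x > template$upper)) return(FALSE)
  open <- all(template$families %in% .open_at_zero)
  !(open && any(x <= 0))
}

# ---- moment-matched starting values -------------------------------------

.moment_start <- function(family, x) {
  m <- mean(x); s <- max(stats::sd(x), 1e-4 * max(abs(m), 1))
  switch(family,
    truncated_normal = c(location = m, scale = s),
    lognormal = {
      lx <- log(x[x > 0])
      c(location = mean(lx), scale = max(stats::sd(lx), 1e-3))
    },
    gamma = {
      shape <- max(m^2 / s^2, 1e-2)
      c(shape = shape, scale = max(m / shape, 1e-8))
    },
    weibull = {
      cv <- s / max(m, 1e-12)
      cv_fun <- function(k) {
        g1 <- gamma(1 + 1 / k); g2 <- gamma(1 + 2 / k)
        sqrt(pmax(g2 / g1^2 - 1, 0)) - cv
      }
      k <- tryCatch(stats::uniroot(cv_fun, c(0.15, 50))$root,
                    error = function(e) 1.5)
      c(shape = k, scale = max(m / gamma(1 + 1 / k), 1e-8))
    },
    truncated_t = c(location = stats::median(x),
                    scale = max(stats::mad(x), 1e-3), df = 3)
  )
}

.template_start <- function(template, x) {
  if (template$type == "single") {
    .to_eta(template$families, .moment_start(template$families, x))
  } else {
    # dominant component matched to the trimmed bulk, second component wider
    qs <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
    bulk <- x[x >= qs[1] & x <= qs[2]]
    if (length(bulk) < 5) bulk <- x
    p1 <- .moment_start(template$families[1], bulk)
    p2 <- .moment_start(template$families[2], x)
    p2["scale"] <- p2["scale"] * 3
    c(stats::qlogis(0.75),
      .to_eta(template$families[1], p1),
      .to_eta(template$families[2], p2))
  }
}

# ---- maximum likelihood -------------------------------------------------

#' Fit a candidate template by constrained maximum likelihood
#'
#' Maximizes the total log-likelihood of a pooled sample under one template
#' over the template's free parameters, via Nelder-Mead restarts from a
#' moment-matched start plus Latin-hypercube-dispersed perturbations in the
#' unconstrained parameterization. The truncation bounds are fixed by the
#' parameter kind and are not free parameters.
#'
#' If any sample point has zero density under the template's support for
#' every parameter value (e.g. an exact 0 under a lognormal, or under a
#' gamma + gamma mixture), the candidate is eliminated: the result carries
#' `loglik = -Inf` and `converged = FALSE`, and no optimization is run.
#' Failed restarts never raise; if all restarts fail the result is flagged
#' non-converged.
#'
#' @param sample A `pooled_sample` from [pool_estimates()] or a bare numeric
#'   vector.
#' @param template A template from [candidate_set()], or a family name
#'   (single fit on `bounds`).
#' @param bounds Support interval used when `template` is a family name
#'   (default `c(0, Inf)`).
#' @param n_starts Number of restarts (default 20).
#' @param seed Integer seed for the restart dispersion.
#' @return A `fit_result`: list with `spec` (fitted [dist_spec()] /
#'   [mixture_spec()], mixtures relabeled so component 1 carries the larger
#'   weight), `loglik`, `k_free`, `aic = 2 k - 2 loglik`, `waic` (`NA` until
#'   [akaike_weights()]), `converged`, `n_restarts_used`, `seed`, `label`.
#' @export
fit_ml <- function(sample, template, bounds = c(0, Inf), n_starts = 20,
                   seed = 1) {
  x <- if (inherits(sample, "pooled_sample")) sample$values else as.numeric(sample)
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  if (is.character(template)) {
    template <- structure(list(type = "single", families = template,
                               lower = bounds[1], upper = bounds[2],
                               label = template), class = "dist_template")
  }
  stopifnot(inherits(template, "dist_template"))

  k_free <- if (template$type == "single") {
    .n_free(structure(list(family = template$families), class = "dist_spec"))
  } else {
    sum(vapply(template$families, function(f)
      if (f == "truncated_t") 3L else 2L, 1L)) + 1L
  }
  res <- list(spec = NULL, loglik = -Inf, k_free = k_free, aic = Inf,
              waic = NA_real_, converged = FALSE, n_restarts_used = 0L,
              seed = seed, label = template$label)
  class(res) <- "fit_result"

  if (!.template_supports(template, x)) return(res)

  # scale floor for mixture components: the mixture likelihood is unbounded
  # as one component collapses onto a data point (scale -> 0), so component
  # scales are kept above 1% of the sample spread
  scale_floor <- if (template$type == "mixture") {
    0.01 * max(stats::sd(x), 1e-12)
  } else 0

  nll <- function(eta) {
    sp <- tryCatch(.spec_from_eta(template, eta), error = function(e) NULL)
    if (is.null(sp)) return(1e10)
    if (scale_floor > 0 &&
        min(sp$component1$params[["scale"]],
            sp$component2$params[["scale"]]) < scale_floor) {
      return(1e10)
    }
    ll <- tryCatch(sum(log_density(sp, x)), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  eta0 <- .template_start(template, x)
  d <- length(eta0)
  set.seed(seed)
  n_lhs <- min(n_starts - 1L, 64L)
  perturb <- if (n_lhs > 0) (lhs::randomLHS(64L, d)[seq_len(n_lhs), , drop = FALSE] - 0.5) * 2 else
    matrix(0, 0, d)
  if (n_starts - 1L > 64L) {
    extra <- matrix(stats::runif((n_starts - 1L - 64L) * d, -1, 1), ncol = d)
    perturb <- rbind(perturb, extra)
  }
  spread <- pmax(0.5, abs(eta0) * 0.3)
  starts <- if (nrow(perturb) > 0) {
    rbind(eta0, sweep(perturb, 2, spread, `*`) +
            matrix(rep(eta0, each = nrow(perturb)), nrow(perturb), d))
  } else {
    matrix(eta0, nrow = 1)
  }

  best_val <- Inf; best_eta <- NULL; any_conv <- FALSE; used <- 0L
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::optim(starts[i, ], nll, method = "Nelder-Mead",
                   control = list(maxit = 500L * d, reltol = 1e-8)),
      error = function(e) NULL)
    used <- used + 1L
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    if (opt$value < best_val) {
      best_val <- opt$value; best_eta <- opt$par
      any_conv <- any_conv || opt$convergence == 0L
    } else {
      any_conv <- any_conv || opt$convergence == 0L
    }
  }
  res$n_restarts_used <- used
  if (is.null(best_eta)) return(res)

  spec <- .spec_from_eta(template, best_eta)
  if (inherits(spec, "mixture_spec") && spec$weight < 0.5) {
    spec <- mixture_spec(1 - spec$weight, spec$component2, spec$component1)
  }
  res$spec <- spec
  res$loglik <- -best_val
  res$aic <- 2 * k_free - 2 * res$loglik
  res$converged <- any_conv
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: loglik %.3f, k %d, AIC %.2f, wAIC %s, %s\n",
              x$label, x$loglik, x$k_free, x$aic,
              ifelse(is.na(x$waic), "-", sprintf("%.3f", x$waic)),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Akaike weights over a candidate comparison set
#'
#' For converged fits, `delta_i = AIC_i - min(AIC)` and
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`; non-converged fits
#' (including support-eliminated candidates) receive weight 0 and are
#' excluded from the normalization. Weights sum to 1 over the converged
#' fits.
#'
#' @param fits List of [fit_ml()] results for one sample.
#' @return The same list with the `waic` field filled.
#' @examples
#' # equal AICs split the weight: {0.5, 0.5}
#' @export
akaike_weights <- function(fits) {
  stopifnot(length(fits) > 0)
  conv <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$aic),
                 logical(1))
  if (!any(conv)) stop("no converged fits in the comparison set", call. = FALSE)
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  delta <- aic - min(aic[conv])
  w <- exp(-delta / 2)
  w[!conv] <- 0
  w <- w / sum(w)
  for (i in seq_along(fits)) fits[[i]]$waic <- w[i]
  fits
}

#' Select the Akaike-weight-best fit
#'
#' Returns the fit with maximal Akaike weight. Exact ties are broken first
#' by fewer free parameters, then by candidate order (the deterministic
#' enumeration order of [candidate_set()]).
#'
#' @param fits List of [fit_ml()] results with `waic` filled (see
#'   [akaike_weights()]).
#' @return The winning `fit_result`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0) stop("empty fit collection", call. = FALSE)
  w <- vapply(fits, function(f) ifelse(is.na(f$waic), -Inf, f$waic), numeric(1))
  k <- vapply(fits, function(f) f$k_free, numeric(1))
  best <- which(w >= max(w) - 1e-12)
  best <- best[order(k[best], best)]
  fits[[best[1]]]
}

#' Extract the proposed prior from a selected fit
#'
#' When the selected model is a two-component mixture, the proposed prior is
#' the component that captures the bulk of the estimates — the one with the
#' larger mixture weight (at an exact 0.5 tie, the component with the
#' smaller variance, logged via a message). Single-family selections pass
#' through with no mixture weight.
#'
#' @param fit A selected `fit_result`.
#' @param sample Optional `pooled_sample` supplying the sample size and
#'   empirical bounds recorded in the prior.
#' @return A `prior_spec`: list with `kind`, `distribution` ([dist_spec()]),
#'   `mixture_weight` (`NA` for single families), `waic`, `n`, `n_source`,
#'   `empirical_lower`, `empirical_upper`.
#' @export
dominant_component <- function(fit, sample = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  spec <- fit$spec
  if (is.null(spec)) stop("cannot extract a prior from an eliminated fit",
                          call. = FALSE)
  if (inherits(spec, "mixture_spec")) {
    if (spec$weight == 0.5) {
      v1 <- .spec_moments(spec$component1)[["var"]]
      v2 <- .spec_moments(spec$component2)[["var"]]
      pick <- if (isTRUE(v2 < v1)) 2L else 1L
      message("mixture weight exactly 0.5; choosing the smaller-variance component (",
              pick, ")")
    } else {
      pick <- 1L  # components are relabeled at fit time so weight >= 0.5
    }
    dist <- if (pick == 1L) spec$component1 else spec$component2
    weight <- if (pick == 1L) spec$weight else 1 - spec$weight
  } else {
    dist <- spec
    weight <- NA_real_
  }
  structure(list(
    kind = if (!is.null(sample)) sample$kind else NA_character_,
    distribution = dist,
    mixture_weight = weight,
    waic = fit$waic,
    selected_label = fit$label,
    n = if (!is.null(sample)) sample$n else NA_integer_,
    n_source = if (!is.null(sample)) sample$n_source else NA_integer_,
    empirical_lower = if (!is.null(sample)) sample$empirical_lower else NA_real_,
    empirical_upper = if (!is.null(sample)) sample$empirical_upper else NA_real_
  ), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  d <- x$distribution
  cat(sprintf("<prior_spec> %s ~ %s(%s) on [%g, %g]%s; n = %s, empirical [%g, %g]\n",
              ifelse(is.na(x$kind), "?", x$kind), d$family,
              paste(sprintf("%s = %.4g", names(d$params), d$params),
                    collapse = ", "),
              d$lower, d$upper,
              ifelse(is.na(x$mixture_weight), "",
                     sprintf(" (mixture weight %.2f)", x$mixture_weight)),
              ifelse(is.na(x$n), "?", x$n),
              x$empirical_lower, x$empirical_upper))
  invisible(x)
}

# machine-readable candidate table for one comparison set
.fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    params <- if (is.null(f$spec)) "" else {
      if (inherits(f$spec, "mixture_spec")) {
        sprintf("w=%.4g; %s; %s", f$spec$weight,
                paste(sprintf("%s=%.6g", names(f$spec$component1$params),
                              f$spec$component1$params), collapse = ","),
                paste(sprintf("%s=%.6g", names(f$spec$component2$params),
                              f$spec$component2$params), collapse = ","))
      } else {
        paste(sprintf("%s=%.6g", names(f$spec$params), f$spec$params),
              collapse = ",")
      }
    }
    data.frame(model = f$label, params = params, loglik = f$loglik,
               k = f$k_free, aic = f$aic, waic = f$waic,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
}
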