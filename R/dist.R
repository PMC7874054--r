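#' Candidate distribution specifications
#'
#' A `dist_spec` describes one candidate density for a pooled sample of
#' parameter estimates: a family, its parameter vector, and a truncation
#' interval `[lower, upper]` over which the density is renormalized. The
#' families are those used to characterize empirical DDM parameter
#' distributions: truncated normal, lognormal, gamma, Weibull, and truncated
#' Student's t (location-scale, with estimated degrees of freedom).
#'
#' Parameter naming follows the usual location/shape + scale convention:
#' \describe{
#'   \item{truncated_normal}{`location` (mean), `scale` (sd) of the parent
#'     normal before truncation.}
#'   \item{lognormal}{`location` (meanlog), `scale` (sdlog).}
#'   \item{gamma}{`shape`, `scale`.}
#'   \item{weibull}{`shape`, `scale`.}
#'   \item{truncated_t}{`location`, `scale`, `df` of the parent location-scale
#'     t; `df` below 1 is permitted.}
#' }
#'
#' The lognormal, gamma and Weibull families have open support at 0: a data
#' point exactly at 0 has zero density (which, during fitting, eliminates the
#' candidate rather than being jittered away).
#'
#' @param family One of `"truncated_normal"`, `"lognormal"`, `"gamma"`,
#'   `"weibull"`, `"truncated_t"`.
#' @param params Named numeric vector of family parameters (see Details).
#' @param lower,upper Truncation bounds, `lower < upper`; `upper` may be `Inf`.
#' @return An object of class `dist_spec`.
#' @seealso [mixture_spec()], [log_density()], [sample_spec()]
#' @examples
#' dist_spec("gamma", c(shape = 11.69, scale = 0.12))
#' dist_spec("truncated_t", c(location = 0.5, scale = 0.05, df = 1.85),
#'           lower = 0, upper = 1)
#' @export
dist_spec <- function(family, params, lower = 0, upper = Inf) {
  family <- match.arg(family, .dist_families)
  params <- unlist(params)
  need <- .family_param_names(family)
  if (!all(need %in% names(params))) {
    stop("family '", family, "' requires parameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  params <- params[need]
  if (!all(is.finite(params))) stop("non-finite distribution parameters", call. = FALSE)
  if (params[["scale"]] <= 0) stop("scale must be > 0", call. = FALSE)
  if (family %in% c("gamma", "weibull") && params[["shape"]] <= 0) {
    stop("shape must be > 0", call. = FALSE)
  }
  if (family == "truncated_t" && params[["df"]] <= 0) {
    stop("df must be > 0", call. = FALSE)
  }
  if (!(lower < upper)) stop("lower must be < upper", call. = FALSE)
  structure(list(family = family, params = params,
                 lower = lower, upper = upper),
            class = "dist_spec")
}

.dist_families <- c("truncated_normal", "lognormal", "gamma", "weibull",
                    "truncated_t")

.family_param_names <- function(family) {
  switch(family,
         truncated_normal = c("location", "scale"),
         lognormal        = c("location", "scale"),
         gamma            = c("shape", "scale"),
         weibull          = c("shape", "scale"),
         truncated_t      = c("location", "scale", "df"))
}

# families whose natural support excludes 0 (open at the origin)
.open_at_zero <- c("lognormal", "gamma", "weibull")

#' Two-component mixture specification
#'
#' A `mixture_spec` is a convex combination `w * f1 + (1 - w) * f2` of two
#' [dist_spec()] densities sharing the same truncation interval. The allowed
#' component pairs are gamma + gamma and truncated normal with each of gamma,
#' lognormal, or another truncated normal; these are the mixtures used to
#' absorb outlier contamination in the empirical distributions while keeping
#' a single dominant mode.
#'
#' @param weight Mixing weight of `component1`, in (0, 1).
#' @param component1,component2 [dist_spec()] objects with identical bounds.
#' @return An object of class `mixture_spec`.
#' @examples
#' g1 <- dist_spec("gamma", c(shape = 12, scale = 0.1))
#' g2 <- dist_spec("gamma", c(shape = 2, scale = 1))
#' mixture_spec(0.76, g1, g2)
#' @export
mixture_spec <- function(weight, component1, component2) {
  stopifnot(inherits(component1, "dist_spec"), inherits(component2, "dist_spec"))
  weight <- unname(weight)
  if (!(weight > 0 && weight < 1)) stop("weight must lie in (0, 1)", call. = FALSE)
  if (component1$lower != component2$lower || component1$upper != component2$upper) {
    stop("mixture components must share truncation bounds", call. = FALSE)
  }
  pair <- sort(c(component1$family, component2$family))
  ok <- identical(pair, c("gamma", "gamma")) ||
    ("truncated_normal" %in% pair &&
       pair[pair != "truncated_normal"][1] %in%
         c("gamma", "lognormal", "truncated_normal") ||
       identical(pair, c("truncated_normal", "truncated_normal")))
  if (!ok) stop("unsupported mixture pair: ", paste(pair, collapse = " + "),
                call. = FALSE)
  structure(list(weight = weight, component1 = component1,
                 component2 = component2,
                 lower = component1$lower, upper = component1$upper),
            class = "mixture_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%s) on [%g, %g]\n", x$family,
              paste(sprintf("%s = %.4g", names(x$params), x$params),
                    collapse = ", "),
              x$lower, x$upper))
  invisible(x)
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> weight %.3f on component 1\n", x$weight))
  print(x$component1); print(x$component2)
  invisible(x)
}

# untruncated log density / cdf / quantile of a family
.d_parent <- function(family, params, x) {
  switch(family,
         truncated_normal = stats::dnorm(x, params[["location"]], params[["scale"]], log = TRUE),
         lognormal = stats::dlnorm(x, params[["location"]], params[["scale"]], log = TRUE),
         gamma = stats::dgamma(x, shape = params[["shape"]], scale = params[["scale"]], log = TRUE),
         weibull = stats::dweibull(x, shape = params[["shape"]], scale = params[["scale"]], log = TRUE),
         truncated_t = stats::dt((x - params[["location"]]) / params[["scale"]],
                                 df = params[["df"]], log = TRUE) - log(params[["scale"]]))
}

.p_parent <- function(family, params, q) {
  switch(family,
         truncated_normal = stats::pnorm(q, params[["location"]], params[["scale"]]),
         lognormal = stats::plnorm(q, params[["location"]], params[["scale"]]),
         gamma = stats::pgamma(q, shape = params[["shape"]], scale = params[["scale"]]),
         weibull = stats::pweibull(q, shape = params[["shape"]], scale = params[["scale"]]),
         truncated_t = stats::pt((q - params[["location"]]) / params[["scale"]],
                                 df = params[["df"]]))
}

.q_parent <- function(family, params, p) {
  switch(family,
         truncated_normal = stats::qnorm(p, params[["location"]], params[["scale"]]),
         lognormal = stats::qlnorm(p, params[["location"]], params[["scale"]]),
         gamma = stats::qgamma(p, shape = params[["shape"]], scale = params[["scale"]]),
         weibull = stats::qweibull(p, shape = params[["shape"]], scale = params[["scale"]]),
         truncated_t = params[["location"]] +
           params[["scale"]] * stats::qt(p, df = params[["df"]]))
}

# probability mass of the parent density on [lower, upper]
.trunc_mass <- function(spec) {
  .p_parent(spec$family, spec$params, spec$upper) -
    .p_parent(spec$family, spec$params, spec$lower)
}

#' Log density of a candidate specification
#'
#' Evaluates the truncated (renormalized) log density of a [dist_spec()] or
#' [mixture_spec()]. Points outside `[lower, upper]` — and, for the
#' open-support families lognormal, gamma and Weibull, points at or below 0 —
#' receive `-Inf`. Mixture densities are combined on the log scale with a
#' stable log-sum-exp.
#'
#' @param spec A [dist_spec()] or [mixture_spec()].
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of log-density values.
#' @examples
#' half_normal <- dist_spec("truncated_normal", c(location = 0, scale = 1))
#' log_density(half_normal, 0)  # log(2 * dnorm(0))
#' @export
log_density <- function(spec, x) UseMethod("log_density")

#' @export
log_density.dist_spec <- function(spec, x) {
  mass <- .trunc_mass(spec)
  if (!is.finite(mass) || mass <= 0) {
    stop("truncation interval has zero probability mass under the parent density",
         call. = FALSE)
  }
  out <- .d_parent(spec$family, spec$params, x) - log(mass)
  out[x < spec$lower | x > spec$upper] <- -Inf
  if (spec$family %in% .open_at_zero) out[x <= 0] <- -Inf
  out
}

#' @export
log_density.mixture_spec <- function(spec, x) {
  l1 <- log_density(spec$component1, x) + log(spec$weight)
  l2 <- log_density(spec$component2, x) + log1p(-spec$weight)
  m <- pmax(l1, l2)
  out <- m + log(exp(l1 - m) + exp(l2 - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Draw from a candidate specification
#'
#' Samples from the truncated density by inverse-CDF sampling restricted to
#' the truncation interval; mixtures first draw a component indicator.
#'
#' @param spec A [dist_spec()] or [mixture_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`, all values inside `[lower, upper]`.
#' @export
sample_spec <- function(spec, n) UseMethod("sample_spec")

#' @export
sample_spec.dist_spec <- function(spec, n) {
  plo <- .p_parent(spec$family, spec$params, spec$lower)
  phi <- .p_parent(spec$family, spec$params, spec$upper)
  u <- stats::runif(n, plo, phi)
  x <- .q_parent(spec$family, spec$params, u)
  pmin(pmax(x, spec$lower), spec$upper)
}

#' @export
sample_spec.mixture_spec <- function(spec, n) {
  take1 <- stats::runif(n) < spec$weight
  x <- numeric(n)
  if (any(take1)) x[take1] <- sample_spec(spec$component1, sum(take1))
  if (any(!take1)) x[!take1] <- sample_spec(spec$component2, sum(!take1))
  x
}

# number of free parameters for AIC: 2 for the two-parameter families, 3 for
# truncated t (df estimated), k1 + k2 + 1 for mixtures; truncation bounds are
# fixed constants, never counted
.n_free <- function(spec) {
  if (inherits(spec, "mixture_spec")) {
    return(.n_free(spec$component1) + .n_free(spec$component2) + 1L)
  }
  if (spec$family == "truncated_t") 3L else 2L
}

# numeric mean/variance of a (possibly mixture) spec via quadrature; used only
# for the equal-weight tie-break when extracting a dominant component
.spec_moments <- function(spec) {
  f <- function(x) exp(log_density(spec, x))
  lo <- max(spec$lower, if (inherits(spec, "mixture_spec")) -Inf else -Inf)
  m1 <- tryCatch(stats::integrate(function(x) x * f(x), lo, spec$upper,
                                  rel.tol = 1e-8)$value, error = function(e) NA_real_)
  m2 <- tryCatch(stats::integrate(function(x) x^2 * f(x), lo, spec$upper,
                                  rel.tol = 1e-8)$value, error = function(e) NA_real_)
  c(mean = m1, var = if (is.na(m1) || is.na(m2)) NA_real_ else m2 - m1^2)
}
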