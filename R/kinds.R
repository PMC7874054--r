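#' Parameter kinds of the diffusion decision model
#'
#' The review tracks nine reported parameter kinds: drift rate `v`, boundary
#' separation `a`, absolute starting point `z`, relative starting point (bias)
#' `z_r = z/a`, non-decision time `T_er`, and the across-trial variabilities
#' `s_v`, `s_z`, `s_z_r = s_z/a`, `s_T_er`. `z` and `s_z` are absolute-scale
#' variants convertible to `z_r` and `s_z_r` given `a`.
#'
#' Each kind belongs to a scaling class that determines how its magnitude
#' responds to the identifiability conventions of a fit:
#' \describe{
#'   \item{accumulation}{`v`, `a`, `z`, `s_v`, `s_z` — proportional to the
#'     moment-to-moment diffusion coefficient `s` and affected by the
#'     measurement (RT) unit through the diffusion scaling law.}
#'   \item{time}{`T_er`, `s_T_er` — plain times, affected only by the RT unit.}
#'   \item{dimensionless}{`z_r`, `s_z_r` — ratios, invariant to both.}
#' }
#'
#' @return `parameter_kinds()` returns a data frame with columns `kind`,
#'   `code` (the token used in corpus files), `scaling_class`, and `canonical`
#'   (whether the kind appears in the canonicalized corpus).
#' @examples
#' parameter_kinds()
#' @export
parameter_kinds <- function() {
  data.frame(
    kind = c("v", "a", "z", "z_r", "T_er", "s_v", "s_z", "s_z_r", "s_T_er"),
    code = c("v", "a", "z", "zr", "ter", "sv", "sz", "szr", "ster"),
    scaling_class = c("accumulation", "accumulation", "accumulation",
                      "dimensionless", "time", "accumulation", "accumulation",
                      "dimensionless", "time"),
    canonical = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# kinds appearing in a fully canonicalized corpus / prior table, in report order
.canonical_kinds <- c("v", "a", "z_r", "T_er", "s_v", "s_z_r", "s_T_er")

.all_kinds <- function() parameter_kinds()$kind

.kind_class <- function(kind) {
  pk <- parameter_kinds()
  pk$scaling_class[match(kind, pk$kind)]
}

.kind_from_code <- function(code) {
  pk <- parameter_kinds()
  pk$kind[match(code, pk$code)]
}

.code_from_kind <- function(kind) {
  pk <- parameter_kinds()
  pk$code[match(kind, pk$kind)]
}

# support interval for each canonical kind: [0, 1] for relative starting
# point quantities, [0, Inf) otherwise
.kind_bounds <- function(kind) {
  if (kind %in% c("z_r", "s_z_r")) c(0, 1) else c(0, Inf)
}
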