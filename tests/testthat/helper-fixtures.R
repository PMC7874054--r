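# Shared fixture builders: small corpora constructed in code.

# one estimate row with sensible defaults, overridable per field
est_row <- function(article_id = "a1", study_id = "s1", condition_id = "c1",
                    participant_id = NA_character_, kind = "v", value = 1.5,
                    s_reported = 1, software = "other", rt_unit = "unknown",
                    reporting_level = "aggregated", constraint_group = "g1",
                    n_participants = NA_integer_, task = NA_character_,
                    population = NA_character_) {
  data.frame(article_id = article_id, study_id = study_id,
             condition_id = condition_id, participant_id = participant_id,
             kind = kind, value = value, s_reported = s_reported,
             software = software, rt_unit = rt_unit,
             reporting_level = reporting_level,
             constraint_group = constraint_group,
             n_participants = n_participants, task = task,
             population = population, stringsAsFactors = FALSE)
}

make_corpus <- function(...) {
  ddm_corpus(do.call(rbind, list(...)), provenance = list(source = "fixture"))
}

# a small but complete single-article corpus: three conditions, constrained
# T_er (one group), free v (three groups), plus a and z_r per condition
toy_article <- function(article_id = "a1", ter = 0.4, v = c(2.1, 1.7, 1.2),
                        a = 1.4, z_r = 0.5, s_reported = 1) {
  rows <- list()
  for (ci in 1:3) {
    cid <- paste0("c", ci)
    rows <- c(rows, list(
      est_row(article_id, condition_id = cid, kind = "v", value = v[ci],
              constraint_group = paste0("v_", cid), s_reported = s_reported),
      est_row(article_id, condition_id = cid, kind = "a", value = a,
              constraint_group = paste0("a_", cid), s_reported = s_reported),
      est_row(article_id, condition_id = cid, kind = "z_r", value = z_r,
              constraint_group = paste0("zr_", cid), s_reported = s_reported),
      est_row(article_id, condition_id = cid, kind = "T_er", value = ter,
              constraint_group = "ter_all", s_reported = s_reported)))
  }
  do.call(rbind, rows)
}

# independent truncated-density oracle: renormalize the untruncated density
# by numerically integrated interval mass (never calls log_density)
oracle_trunc_logpdf <- function(dfun, x, lower, upper) {
  mass <- stats::integrate(dfun, lower, upper, rel.tol = 1e-12)$value
  log(dfun(x)) - log(mass)
}

# closed-form mean exit time of a drift-diffusion process from [0, a] with
# drift v, diffusion coefficient s, start z (unconditional on boundary)
wiener_mean_exit <- function(v, a, z, s = 1) {
  if (v == 0) return((z * (a - z)) / s^2)
  k <- 2 * v / s^2
  (a / v) * (1 - exp(-k * z)) / (1 - exp(-k * a)) - z / v
}
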