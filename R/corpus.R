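#' @keywords internal
"_PACKAGE"

# documented corpus file schema, in column order
.corpus_columns <- c("article_id", "study_id", "condition_id", "participant_id",
                     "kind", "value", "s_reported", "software", "rt_unit",
                     "reporting_level", "constraint_group", "n_participants",
                     "task", "population")

.softwares <- c("DMAT", "HDDM", "fastDM", "other", "unknown")
.rt_units <- c("seconds", "milliseconds", "unknown")
.reporting_levels <- c("individual", "aggregated", "group_level")

#' Construct a corpus of reported parameter estimates
#'
#' A corpus holds one row per reported DDM parameter estimate, together with
#' the article-level reporting conventions needed to canonicalize it: the
#' scaling parameter `s` under which it was estimated, the estimation
#' software, the RT unit (per parameter, since articles sometimes report
#' `T_er` in milliseconds and everything else in seconds), the reporting
#' level, and the constraint group tying together rows that repeat one
#' parameter held fixed across conditions.
#'
#' @param estimates Data frame with columns `article_id`, `study_id`,
#'   `condition_id`, `participant_id`, `kind`, `value`, `s_reported`,
#'   `software`, `rt_unit`, `reporting_level`, `constraint_group`,
#'   `n_participants`, `task`, `population`. `kind` uses the internal names
#'   from [parameter_kinds()]. Unknown/absent entries are `NA`.
#' @param provenance Named list of free-text metadata (e.g. source file).
#' @return An object of class `ddm_corpus` with elements `estimates` and
#'   `provenance`.
#' @seealso [read_corpus()], [write_corpus()], [validate_plausibility()]
#' @export
ddm_corpus <- function(estimates, provenance = list()) {
  missing_cols <- setdiff(.corpus_columns, names(estimates))
  if (length(missing_cols)) {
    stop("corpus schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  estimates <- as.data.frame(estimates, stringsAsFactors = FALSE)
  rownames(estimates) <- NULL

  bad_kind <- !(estimates$kind %in% .all_kinds())
  if (any(bad_kind)) {
    stop("unknown parameter kind(s): ",
         paste(unique(estimates$kind[bad_kind]), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(estimates$value) || any(!is.finite(estimates$value))) {
    stop("corpus validation error: 'value' must be finite numeric", call. = FALSE)
  }
  if (any(!is.na(estimates$s_reported) & estimates$s_reported <= 0)) {
    stop("corpus validation error: s_reported must be > 0 when known", call. = FALSE)
  }
  lvl <- estimates$reporting_level
  if (any(!is.na(lvl) & !(lvl %in% .reporting_levels))) {
    stop("corpus validation error: invalid reporting_level", call. = FALSE)
  }
  ind <- !is.na(lvl) & lvl == "individual"
  if (any(ind & (is.na(estimates$participant_id) | estimates$participant_id == ""))) {
    stop("corpus validation error: individual rows must carry participant_id",
         call. = FALSE)
  }
  if (any(!ind & !is.na(estimates$participant_id) & estimates$participant_id != "")) {
    stop("corpus validation error: aggregated/group_level rows must not carry participant_id",
         call. = FALSE)
  }
  if (any(is.na(estimates$constraint_group) | estimates$constraint_group == "")) {
    stop("corpus validation error: constraint_group must be non-empty", call. = FALSE)
  }
  key <- .corpus_key(estimates)
  if (anyDuplicated(key)) {
    stop("corpus validation error: duplicate (article_id, study_id, condition_id, ",
         "participant_id, kind) tuple(s): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "), call. = FALSE)
  }
  structure(list(estimates = estimates, provenance = provenance),
            class = "ddm_corpus")
}

.corpus_key <- function(df) {
  pid <- ifelse(is.na(df$participant_id), "", df$participant_id)
  paste(df$article_id, df$study_id, df$condition_id, pid, df$kind, sep = "\r")
}

#' @export
print.ddm_corpus <- function(x, ...) {
  df <- x$estimates
  cat(sprintf("<ddm_corpus> %d estimate(s) from %d article(s)\n",
              nrow(df), length(unique(df$article_id))))
  if (nrow(df)) {
    tab <- table(df$kind)
    cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), unlist(x$provenance),
                               sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Read a corpus file
#'
#' Reads a UTF-8 delimited corpus of extracted parameter estimates (comma by
#' default, tab accepted). The header must contain the documented schema
#' columns; unknown extra columns are preserved in the corpus provenance.
#' Empty strings denote unknown/absent values. `kind` tokens in the file are
#' `v|a|z|zr|ter|sv|sz|szr|ster`.
#'
#' @param path Path to the file.
#' @param dialect `"comma"` or `"tab"`.
#' @return A [ddm_corpus()].
#' @export
read_corpus <- function(path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  sep <- if (dialect == "comma") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           na.strings = NULL, comment.char = "")
  missing_cols <- setdiff(.corpus_columns, names(raw))
  if (length(missing_cols)) {
    stop("corpus schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), .corpus_columns)

  df <- raw[, .corpus_columns, drop = FALSE]
  n <- nrow(df)

  value <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(value))
  if (length(bad)) {
    stop("corpus parse error: non-numeric 'value' in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (e.g. \"", df$value[bad[1]], "\")", call. = FALSE)
  }
  s_rep <- suppressWarnings(as.numeric(df$s_reported))
  bad_s <- which(is.na(s_rep) & df$s_reported != "")
  if (length(bad_s)) {
    stop("corpus parse error: non-numeric 's_reported' in row(s) ",
         paste(utils::head(bad_s, 5), collapse = ", "), call. = FALSE)
  }
  npart <- suppressWarnings(as.integer(df$n_participants))
  bad_n <- which(is.na(npart) & df$n_participants != "")
  if (length(bad_n)) {
    stop("corpus parse error: non-integer 'n_participants' in row(s) ",
         paste(utils::head(bad_n, 5), collapse = ", "), call. = FALSE)
  }

  kind <- .kind_from_code(df$kind)
  bad_k <- which(is.na(kind))
  if (length(bad_k)) {
    stop("corpus parse error: unknown kind token in row(s) ",
         paste(utils::head(bad_k, 5), collapse = ", "),
         " (e.g. \"", df$kind[bad_k[1]], "\")", call. = FALSE)
  }

  blank_na <- function(x) ifelse(x == "", NA_character_, x)
  est <- data.frame(
    article_id = df$article_id,
    study_id = df$study_id,
    condition_id = df$condition_id,
    participant_id = blank_na(df$participant_id),
    kind = kind,
    value = value,
    s_reported = s_rep,
    software = ifelse(df$software == "", "unknown", df$software),
    rt_unit = ifelse(df$rt_unit == "", "unknown", df$rt_unit),
    reporting_level = ifelse(df$reporting_level == "", "aggregated",
                             df$reporting_level),
    constraint_group = df$constraint_group,
    n_participants = npart,
    task = blank_na(df$task),
    population = blank_na(df$population),
    stringsAsFactors = FALSE
  )
  prov <- list(source = path, n_rows = n)
  if (length(extra)) prov$extra_columns <- raw[, extra, drop = FALSE]
  ddm_corpus(est, prov)
}

#' Write a corpus file
#'
#' Serializes a corpus back to the documented delimited format; reading the
#' file back reproduces the corpus field-for-field. `NA` fields become empty
#' strings; values are printed with full (17 significant digit) precision so
#' the round trip is exact.
#'
#' @param corpus A [ddm_corpus()].
#' @param path Output file path.
#' @param dialect `"comma"` or `"tab"`.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path, dialect = c("comma", "tab")) {
  stopifnot(inherits(corpus, "ddm_corpus"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  df <- corpus$estimates
  na_blank <- function(x) ifelse(is.na(x), "", as.character(x))
  out <- data.frame(
    article_id = df$article_id,
    study_id = df$study_id,
    condition_id = df$condition_id,
    participant_id = na_blank(df$participant_id),
    kind = .code_from_kind(df$kind),
    value = sprintf("%.17g", df$value),
    s_reported = ifelse(is.na(df$s_reported), "", sprintf("%.17g", df$s_reported)),
    software = ifelse(df$software == "unknown", "", df$software),
    rt_unit = ifelse(df$rt_unit == "unknown", "", df$rt_unit),
    reporting_level = df$reporting_level,
    constraint_group = df$constraint_group,
    n_participants = na_blank(df$n_participants),
    task = na_blank(df$task),
    population = na_blank(df$population),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = sep, row.names = FALSE, quote = TRUE,
                     qmethod = "double")
  invisible(path)
}

#' Flag implausible estimates
#'
#' Screens a corpus for estimates that fall outside the parameters'
#' theoretical bounds after canonicalization — e.g. a negative boundary
#' separation, a relative starting point outside `[0, 1]`, or a negative
#' variability parameter — and, optionally, for per-article inconsistency
#' between the inferred RT unit of `T_er` and that of the remaining
#' parameters. Flagging is purely diagnostic: the corpus is never modified;
#' exclusion happens in a separate, logged pipeline stage.
#'
#' Zero is attainable for `T_er` and the variability parameters (the
#' empirical lower bound of `T_er` across the literature is 0), so exact
#' zeros are not flagged.
#'
#' @param corpus A [ddm_corpus()], raw or canonicalized.
#' @param check_units If `TRUE`, additionally run the two-step RT-unit
#'   inference per article and flag articles whose `T_er` unit disagrees with
#'   the unit of the remaining parameters (a mixed-unit article, legal but
#'   worth auditing).
#' @return Data frame of flags with columns `row`, `article_id`, `kind`,
#'   `rule`, `message`; zero rows when nothing is implausible.
#' @export
validate_plausibility <- function(corpus, check_units = FALSE) {
  stopifnot(inherits(corpus, "ddm_corpus"))
  df <- corpus$estimates
  flags <- list()
  add <- function(rows, rule, message) {
    if (length(rows)) {
      flags[[length(flags) + 1L]] <<- data.frame(
        row = rows, article_id = df$article_id[rows], kind = df$kind[rows],
        rule = rule, message = message, stringsAsFactors = FALSE)
    }
  }
  add(which(df$kind == "a" & df$value <= 0), "a_nonpositive",
      "boundary separation negative or zero")
  add(which(df$kind == "T_er" & df$value < 0), "ter_negative",
      "non-decision time negative")
  add(which(df$kind %in% c("z_r", "s_z_r") & (df$value < 0 | df$value > 1)),
      "relative_outside_unit", "relative starting-point quantity outside [0, 1]")
  add(which(df$kind %in% c("s_v", "s_z", "s_T_er") & df$value < 0),
      "variability_negative", "across-trial variability negative")
  add(which(df$kind == "z" & df$value < 0), "z_negative",
      "absolute starting point negative")

  if (check_units && nrow(df)) {
    for (art in unique(df$article_id)) {
      sub <- df[df$article_id == art, , drop = FALSE]
      units <- infer_rt_units(sub)
      u_ter <- units$unit[units$kind == "T_er"]
      u_rest <- units$unit[units$kind == "v"]
      if (length(u_ter) && length(u_rest) &&
          !is.na(u_ter) && !is.na(u_rest) && u_ter != u_rest) {
        flags[[length(flags) + 1L]] <- data.frame(
          row = NA_integer_, article_id = art, kind = NA_character_,
          rule = "mixed_units",
          message = sprintf("inferred T_er unit (%s) differs from remaining parameters (%s)",
                            u_ter, u_rest),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(flags)) do.call(rbind, flags) else
    data.frame(row = integer(), article_id = character(), kind = character(),
               rule = character(), message = character(), stringsAsFactors = FALSE)
}
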