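#' Two-group comparison of one cohort variable
#'
#' Continuous variables are compared with a two-sample t-test (pooled
#' variance by default, Welch by flag); categorical variables (sex) with
#' a chi-square test on the 2x2 table (no continuity correction by
#' default). Group means and standard errors (or frequencies and
#' percentages) are reported alongside the test.
#'
#' @param cohort a data frame with a `group` column (`"CS"`/`"O-LOAD"`).
#' @param variable column name to compare.
#' @param test `"t"` or `"chisq"`.
#' @param var_equal pooled-variance t-test (default) vs Welch.
#' @param correct continuity correction for the chi-square test.
#' @return one-row data frame: `variable`, `mean_cs`, `se_cs`,
#'   `mean_oload`, `se_oload`, `statistic`, `p`, `test`, `n_cs`,
#'   `n_oload`. For `"chisq"` the mean/SE columns hold the frequency and
#'   percentage of the first level.
#' @export
compare_groups <- function(cohort, variable, test = c("t", "chisq"),
                           var_equal = TRUE, correct = FALSE) {
  test <- match.arg(test)
  if (!variable %in% names(cohort)) stopf("no column '%s' in cohort", variable)
  g <- cohort$group
  if (!all(COHORT_GROUPS %in% g)) stopf("both group labels must be present")
  x <- cohort[[variable]]
  cs <- x[g == "CS" & !is.na(x)]
  ol <- x[g == "O-LOAD" & !is.na(x)]
  if (test == "t") {
    if (length(cs) < 2 || length(ol) < 2) stopf("need >= 2 observations per group")
    if (var(cs) == 0 && var(ol) == 0) stopf("zero variance in both groups: t undefined")
    tt <- t.test(cs, ol, var.equal = var_equal)
    data.frame(variable = variable,
               mean_cs = mean(cs), se_cs = sd(cs) / sqrt(length(cs)),
               mean_oload = mean(ol), se_oload = sd(ol) / sqrt(length(ol)),
               statistic = unname(tt$statistic), p = tt$p.value,
               test = if (var_equal) "t" else "t_welch",
               n_cs = length(cs), n_oload = length(ol))
  } else {
    tab <- table(factor(g[!is.na(x)]), factor(x[!is.na(x)]))
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    lev1 <- colnames(tab)[1]
    data.frame(variable = variable,
               mean_cs = tab["CS", lev1],
               se_cs = 100 * tab["CS", lev1] / sum(tab["CS", ]),
               mean_oload = tab["O-LOAD", lev1],
               se_oload = 100 * tab["O-LOAD", lev1] / sum(tab["O-LOAD", ]),
               statistic = unname(ct$statistic), p = ct$p.value,
               test = "chisq", n_cs = sum(tab["CS", ]), n_oload = sum(tab["O-LOAD", ]))
  }
}

#' Pearson correlation screen with Bonferroni control
#'
#' Every physiology x cognition pair is tested with a two-sided Pearson
#' correlation on pairwise-complete observations. The Bonferroni family
#' size `m` defaults to the number of tests actually performed in this
#' call (a "block"); it can be fixed explicitly to treat several calls as
#' one family. `m` is recorded in every row, so the flag is auditable.
#'
#' @param data data frame holding both variable sets (typically one
#'   group's rows of a cohort joined with derived physiology).
#' @param phys_vars,cog_vars column name vectors.
#' @param alpha family-wise significance level.
#' @param m Bonferroni family size; `NULL` = number of tests performed.
#' @param min_n minimum paired complete observations per cell.
#' @return data frame of cells: `phys`, `cog`, `n`, `r`, `p`, `m`,
#'   `bonferroni` (logical flag, `p <= alpha / m`).
#' @export
correlate_cells <- function(data, phys_vars, cog_vars, alpha = 0.05,
                            m = NULL, min_n = 4) {
  miss <- setdiff(c(phys_vars, cog_vars), names(data))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  cells <- expand.grid(phys = phys_vars, cog = cog_vars,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    x <- data[[cells$phys[i]]]
    y <- data[[cells$cog[i]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_n)
      return(data.frame(phys = cells$phys[i], cog = cells$cog[i],
                        n = sum(ok), r = NA_real_, p = NA_real_))
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
      stopf("zero variance in %s or %s", cells$phys[i], cells$cog[i])
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(phys = cells$phys[i], cog = cells$cog[i], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  performed <- sum(!is.na(out$p))
  out$m <- if (is.null(m)) performed else m
  out$bonferroni <- !is.na(out$p) & out$p <= alpha / out$m
  out
}

#' Fisher-z confidence/sampling interval for a correlation
#'
#' @param r correlation (true or observed).
#' @param n sample size.
#' @param level coverage.
#' @return length-2 vector of correlation bounds.
#' @export
fisher_z_interval <- function(r, n, level = 0.95) {
  if (n <= 3) stopf("need n > 3")
  zc <- stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(r)
  tanh(z + c(-1, 1) * zc / sqrt(n - 3))
}

#' Unwrap clock hours around a reference for linear statistics
#'
#' Acrophases and sleep onset times live on a 24-h circle; before a
#' t-test they are mapped to `reference + (-12, 12]` so a cluster
#' straddling midnight is not split.
#'
#' @param hours clock hours in `[0, 24)`.
#' @param reference centre of the linearized scale; default the circular
#'   mean of `hours`.
#' @return numeric vector, possibly outside `[0, 24)`.
#' @export
unwrap_clock <- function(hours, reference = NULL) {
  if (is.null(reference)) reference <- circ_mean_clock(hours)
  reference + clock_diff(reference, hours)
}

#' Group-comparison and correlation reports for a cohort
#'
#' Builds the two standard reports: per-variable group comparisons
#' (demographics, scores, sleep, temperature rhythm and state-wise HRV)
#' and the within-group correlation screen between HRV physiology and
#' cognitive scores, Bonferroni-flagged per state block.
#'
#' @param cohort a [cohort_table()] including score columns.
#' @param derived the [analyze_cohort()] output (joined on `id`).
#' @param alpha significance level.
#' @param cor_group group whose correlation structure is screened
#'   (default `"O-LOAD"`).
#' @param family Bonferroni family: `"block"` (per state block, default)
#'   or `"table"` (all blocks as one family).
#' @return list with `comparisons` (data frame of [compare_groups()]
#'   rows) and `correlations` (data frame of [correlate_cells()] rows
#'   with a `state` column).
#' @export
build_tables <- function(cohort, derived, alpha = 0.05,
                         cor_group = "O-LOAD", family = c("block", "table")) {
  family <- match.arg(family)
  if (!all(COHORT_GROUPS %in% cohort$group))
    stopf("both groups must be non-empty")
  full <- merge(cohort, derived, by = "id", all.x = TRUE)
  full <- full[order(match(full$id, cohort$id)), ]

  score_cols <- intersect(c("Education", "CRQ", "Hachinski", "BDI", "HDRS",
                            "PSQI", "ESS", "MMSE", "Clock", "Vocabulary",
                            "SemanticFluency", "RAVLT", "RAVLT_D"),
                          names(full))
  sleep_cols <- intersect(c("duration_asleep", "time_awake", "efficiency"),
                          names(full))
  temp_cols <- intersect(c("pct_rhythm", "mesor", "amplitude"), names(full))
  hrv_fields <- c("rrm", "sdnn", "rmssd", "ln_vlf", "ln_lf", "ln_hf",
                  "lh_ratio", "lf_nu", "hf_nu")
  hrv_cols <- intersect(as.vector(outer(c("wake_", "sleep_", "diff_"),
                                        hrv_fields, paste0)), names(full))
  comp_vars <- c("age", score_cols, sleep_cols, temp_cols, hrv_cols)
  comps <- do.call(rbind, lapply(comp_vars, function(v)
    tryCatch(compare_groups(full, v), error = function(e) NULL)))
  if ("sex" %in% names(full))
    comps <- rbind(compare_groups(full, "sex", test = "chisq"), comps)
  # circular variables handled on the unwrapped scale
  for (v in intersect(c("acrophase", "start_time", "end_time"), names(full))) {
    u <- full
    u[[v]] <- unwrap_clock(full[[v]])
    row <- tryCatch(compare_groups(u, v), error = function(e) NULL)
    if (!is.null(row)) comps <- rbind(comps, row)
  }

  sub <- full[full$group == cor_group, , drop = FALSE]
  cogs <- intersect(c("CRQ", "MMSE", "Clock", "Vocabulary", "SemanticFluency",
                      "RAVLT", "RAVLT_D"), names(sub))
  blocks <- list(wake = paste0("wake_", c("sdnn", "rmssd", "ln_lf", "ln_hf", "lh_ratio")),
                 sleep = paste0("sleep_", c("sdnn", "rmssd", "ln_lf", "ln_hf", "lh_ratio")),
                 diff = paste0("diff_", c("sdnn", "rmssd", "ln_lf", "ln_hf", "lh_ratio")))
  m_table <- if (family == "table") length(blocks) * length(cogs) * 5 else NULL
  cors <- do.call(rbind, lapply(names(blocks), function(b) {
    cc <- correlate_cells(sub, intersect(blocks[[b]], names(sub)), cogs,
                          alpha = alpha, m = m_table)
    if (nrow(cc)) cc$state <- b
    cc
  }))
  list(comparisons = comps, correlations = cors)
}
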