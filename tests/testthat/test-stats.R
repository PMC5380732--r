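mk_cohort <- function(cs, oload, var = "x") {
  df <- data.frame(id = sprintf("s%02d", seq_len(length(cs) + length(oload))),
                   group = c(rep("CS", length(cs)), rep("O-LOAD", length(oload))),
                   sex = "F", age = 50)
  df[[var]] <- c(cs, oload)
  df
}

test_that("group t-test matches the pooled-variance formula", {
  co <- mk_cohort(c(1, 2, 3), c(4, 5, 6))
  row <- compare_groups(co, "x")
  # direct pooled formula
  sp2 <- (2 * var(c(1, 2, 3)) + 2 * var(c(4, 5, 6))) / 4
  t_direct <- (mean(c(1, 2, 3)) - mean(c(4, 5, 6))) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(row$statistic, t_direct)
  expect_equal(row$p, 2 * pt(-abs(t_direct), df = 4))
  expect_equal(row$mean_cs, 2)
  expect_equal(row$se_cs, 1 / sqrt(3))
})

test_that("identical groups give t = 0, p = 1 and degenerate input errors", {
  co <- mk_cohort(c(1, 2, 3), c(1, 2, 3))
  row <- compare_groups(co, "x")
  expect_equal(row$statistic, 0)
  expect_equal(row$p, 1)
  expect_error(compare_groups(mk_cohort(c(1, 1), c(1, 1)), "x"), "zero variance")
  expect_error(compare_groups(co, "nope"), "no column")
  expect_error(compare_groups(co[co$group == "CS", ], "x"), "both group")
})

test_that("chi-square on sex composition reports frequencies", {
  co <- mk_cohort(rnorm(10), rnorm(12))
  co$sex <- c(rep("F", 7), rep("M", 3), rep("F", 5), rep("M", 7))
  row <- compare_groups(co, "sex", test = "chisq")
  expect_equal(row$test, "chisq")
  tab <- table(co$group, co$sex)
  expect_equal(row$statistic,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic))
  expect_equal(row$mean_cs, 7)      # F count
  expect_equal(row$se_cs, 70)       # % F
})

test_that("Pearson cells match the direct formula and flag by p <= alpha/m", {
  df <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 5), c = c(1, 2, 3, 4, 5))
  cells <- correlate_cells(df, "a", c("b", "c"))
  expect_equal(cells$r[cells$cog == "b"], 0.8)
  expect_equal(cells$r[cells$cog == "c"], 1)
  expect_lt(cells$p[cells$cog == "c"], 1e-8)
  expect_equal(unique(cells$m), 2)
  expect_equal(cells$bonferroni, cells$p <= 0.05 / cells$m)
})

test_that("Bonferroni flags are monotone non-increasing in the family size", {
  set.seed(61)
  df <- as.data.frame(matrix(rnorm(30 * 8), 30))
  names(df) <- c(paste0("p", 1:4), paste0("c", 1:4))
  df$p1 <- df$c1 + rnorm(30, 0, 0.4)    # one real association
  small_m <- correlate_cells(df, paste0("p", 1:4), paste0("c", 1:4), m = 4)
  big_m <- correlate_cells(df, paste0("p", 1:4), paste0("c", 1:4), m = 100)
  expect_lte(sum(big_m$bonferroni), sum(small_m$bonferroni))
  expect_gte(sum(small_m$bonferroni), 1)
})

test_that("missing data are dropped cell-wise and tiny cells return NA", {
  df <- data.frame(a = c(1, 2, NA, 4, 5, 6), b = c(2, 1, 4, NA, 5, 7),
                   c = c(1, NA, NA, NA, 2, 3))
  cells <- correlate_cells(df, "a", c("b", "c"))
  expect_equal(cells$n[cells$cog == "b"], 4)
  expect_true(is.na(cells$r[cells$cog == "c"]))   # only 3 complete pairs
  expect_error(correlate_cells(data.frame(a = 1:5, b = rep(2, 5)), "a", "b"),
               "zero variance")
})

test_that("fisher intervals cover the generating correlation", {
  ci <- fisher_z_interval(-0.744, 23)
  expect_lt(ci[1], -0.744)
  expect_gt(ci[2], -0.744)
  expect_error(fisher_z_interval(0.5, 3), "n > 3")
})

test_that("clock unwrapping keeps midnight-straddling phases comparable", {
  h <- c(23.5, 0.5, 23.8, 0.2)
  u <- unwrap_clock(h)
  expect_lt(diff(range(u)), 2)
  expect_equal(unwrap_clock(h, reference = 0), c(-0.5, 0.5, -0.2, 0.2))
})

test_that("a programmed phase delay is detected at the study group sizes", {
  # power of the group comparison at n = 19/31 with the programmed
  # 1.24-h delay and realistic between-subject spread
  set.seed(67)
  hits <- replicate(300, {
    co <- mk_cohort(rnorm(19, 2.56, 1.82), rnorm(31, 3.80, 1.33), var = "acro")
    compare_groups(co, "acro")$p < 0.05
  })
  expect_gte(mean(hits), 0.6)
})

test_that("report builder mirrors the cohort structure and flags by family", {
  ol <- default_subject_spec("O-LOAD")
  ol$inject_r <- 0
  co <- gen_cohort(cohort_spec(n_cs = 5, n_oload = 6, seed = 91, days = 2,
                               rr_hours = 2, oload = ol), analyze = FALSE)
  # minimal synthetic derived table (pipeline output schema)
  set.seed(92)
  n <- nrow(co$cohort)
  derived <- data.frame(id = co$cohort$id, pct_rhythm = runif(n, 20, 30),
                        mesor = rnorm(n, 33, 0.5), amplitude = runif(n, 0.8, 1.1),
                        acrophase = rnorm(n, 3, 1) %% 24,
                        start_time = rnorm(n, 0.5, 0.3) %% 24,
                        end_time = rnorm(n, 7.9, 0.3),
                        duration_asleep = rnorm(n, 450, 20),
                        time_awake = rnorm(n, 25, 5),
                        efficiency = runif(n, 92, 98))
  for (st in c("wake", "sleep", "diff")) {
    for (f in c("rrm", "sdnn", "rmssd", "ln_vlf", "ln_lf", "ln_hf",
                "lh_ratio", "lf_nu", "hf_nu"))
      derived[[paste0(st, "_", f)]] <- rnorm(n)
  }
  rep <- build_tables(co$cohort, derived)
  expect_true(all(c("RAVLT", "efficiency", "amplitude", "acrophase",
                    "sleep_rrm", "diff_lh_ratio") %in% rep$comparisons$variable))
  expect_true(all(rep$correlations$bonferroni ==
                    (!is.na(rep$correlations$p) &
                       rep$correlations$p <= 0.05 / rep$correlations$m)))
  expect_equal(sort(unique(rep$correlations$state)), c("diff", "sleep", "wake"))
  bad <- co$cohort[co$cohort$group == "CS", ]
  expect_error(build_tables(bad, derived), "both groups")
})
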