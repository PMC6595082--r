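# PVC records, exclusion, averaging, distances, ANOVA, power analysis.

test_that("pvc is the exact relative volume change in percent", {
  expect_equal(pvc(1000, 950), -5)
  expect_equal(pvc(3000, 3000), 0)
  expect_equal(pvc(2412.7, 2291.5), (2291.5 - 2412.7) / 2412.7 * 100,
               tolerance = 1e-12)
  expect_error(pvc(0, 10), "positive")
  expect_error(pvc(-5, 10), "positive")
})

test_that("exclusion flags strictly beyond the threshold, without deleting", {
  pvcs <- c(-26, -25, 25, 25.01, 0, 10, -24.9, 60, -30, 3)
  rec <- toy_records(pvcs,
                     subjects = rep(sprintf("S%d", 1:5), each = 2),
                     groups = rep(c("CTRL", "AD"), 5),
                     scans = rep(c("A", "B"), 5),
                     sides = rep(c("L", "R"), each = 5))
  tab <- suppressMessages(apply_exclusion(cohort_table(rec)))
  expect_equal(sum(tab$excluded), 4)          # -26, 25.01, 60, -30
  expect_false(tab$excluded[2])               # exactly -25 kept
  expect_equal(nrow(tab), 10)                 # nothing deleted
  expect_equal(sum(!tab$excluded), 6)
})

test_that("subject PVC averages sides and drops incomplete subject-scans", {
  rec <- toy_records(c(-4, -2, -6, -30),
                     subjects = c("S1", "S1", "S2", "S2"),
                     groups = "MCI", scans = "A",
                     sides = c("L", "R", "L", "R"))
  tab <- suppressMessages(apply_exclusion(cohort_table(rec)))
  sp <- suppressMessages(subject_pvc(tab))
  expect_equal(sp$pvc[sp$subject_id == "S1"], -3)
  expect_false("S2" %in% sp$subject_id)       # R side flagged -> omitted
})

test_that("subject PVC equals a brute-force group-by mean on random tables", {
  set.seed(11)
  n <- 24
  rec <- toy_records(rnorm(n, -3, 4),
                     subjects = rep(sprintf("S%d", 1:6), each = 4),
                     groups = rep(c("CTRL", "MCI", "AD"), each = 8),
                     scans = rep(rep(c("A", "B"), each = 2), 6),
                     sides = rep(c("L", "R"), 12))
  tab <- cohort_table(rec)
  sp <- subject_pvc(tab)
  for (r in seq_len(nrow(sp))) {
    sel <- rec$subject_id == sp$subject_id[r]
    sel <- sel & rep(rep(c("A", "B"), each = 2), 6) == sp$scan[r]
    expect_equal(sp$pvc[r], mean(pvc(rec$v_bl[sel], rec$v_fu[sel])))
  }
})

test_that("average distances match brute-force RMS and its properties", {
  expect_equal(d_ave_scans(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(d_ave_scans(c(0, 2), c(2, 0)), 2)
  x <- c(-1.2, 0.5, -4); y <- c(0.3, -2, -3.5)
  expect_equal(d_ave_scans(x, y), sqrt(mean((x - y)^2)))
  expect_equal(d_ave_methods(x, y), d_ave_methods(y, x))
  expect_equal(d_ave_methods(x, x), 0)
  # linear scaling of all PVCs scales the distance linearly
  expect_equal(d_ave_scans(3 * x, 3 * y), 3 * d_ave_scans(x, y))
  expect_error(d_ave_scans(1:3, 1:4), "length")
})

test_that("replicate noise appears in the scan distance as sqrt(2) sigma", {
  set.seed(123)
  n <- 160; sig <- 1.5
  truth <- rnorm(n, -2, 3)
  a <- truth + rnorm(n, 0, sig); b <- truth + rnorm(n, 0, sig)
  d <- d_ave_scans(a, b)
  expected <- sqrt(2) * sig
  # RMS of n chi-type draws: sd(d) ~ d / sqrt(2 n); allow 3 sigma
  expect_lt(abs(d - expected), 3 * expected / sqrt(2 * n))
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(5)
  base <- toy_records(rnorm(16, -3, 2),
                      subjects = rep(sprintf("S%d", 1:4), each = 4),
                      groups = "MCI",
                      scans = rep(rep(c("A", "B"), each = 2), 4),
                      sides = rep(c("L", "R"), 8), method = "m1")
  m2 <- base; m2$method <- "m2"; m2$v_fu <- m2$v_fu * 1.001
  m3 <- base; m3$method <- "m3"
  tab <- cohort_table(rbind(base, m2, m3))
  dm <- distance_matrix(tab)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), setNames(rep(0, 3), c("m1", "m2", "m3")))
  expect_equal(dm["m1", "m3"], 0)            # identical methods
  # entries equal direct pairwise computation
  sp <- subject_pvc(tab)
  p1 <- sp$pvc[sp$method == "m1"]; p2 <- sp$pvc[sp$method == "m2"]
  expect_equal(dm["m1", "m2"], d_ave_methods(p1, p2))
  expect_gt(dm["m1", "m2"], 0)
})

test_that("pooled ANOVA equals explicit sums of squares and t^2", {
  # textbook-style 3-group table, oracle computed by explicit sums of squares
  vals <- c(6.2, 5.9, 7.1, 6.5, 5.5,   4.1, 4.8, 3.9, 5.0, 4.4,
            5.1, 5.6, 4.9, 6.0, 5.2)
  grp <- rep(c("g1", "g2", "g3"), each = 5)
  df <- data.frame(subject_id = sprintf("S%d", 1:15), group = grp,
                   scan = "A", pvc = vals)
  oracle <- brute_force_anova(vals, grp)
  got <- group_anova(df)
  expect_equal(got$F, oracle$F, tolerance = 1e-12)
  expect_equal(got$df_between, oracle$df_between)
  expect_equal(got$df_error, oracle$df_error)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
  expect_true(all(got$posthoc$p_adj >= 0 & got$posthoc$p_adj <= 1))

  # equal group means -> F exactly 0
  df0 <- data.frame(subject_id = sprintf("S%d", 1:8),
                    group = rep(c("a", "b"), each = 4),
                    scan = "A", pvc = rep(c(-1, 1, -2, 2), 2))
  expect_equal(group_anova(df0)$F, 0, tolerance = 1e-12)

  # two groups: F = t^2 of the equal-variance t test
  set.seed(2)
  df2 <- data.frame(subject_id = sprintf("S%d", 1:20),
                    group = rep(c("CTRL", "AD"), each = 10),
                    scan = "A", pvc = c(rnorm(10, -1, 2), rnorm(10, -4, 2)))
  tt <- t.test(pvc ~ group, data = df2, var.equal = TRUE)
  expect_equal(group_anova(df2)$F, unname(tt$statistic^2), tolerance = 1e-10)

  expect_error(group_anova(df2[df2$group == "CTRL", ]), "two groups")
})

test_that("mixed-mode ANOVA tests group between subjects", {
  tab <- simulate_cohort(cohort_spec(seed = 9))
  sp <- suppressMessages(subject_pvc(tab))
  mx <- group_anova(sp, mode = "mixed")
  expect_equal(mx$df_between, 2)
  expect_equal(mx$df_error, 77)              # 80 subjects - 3 groups
  expect_true(is.finite(mx$scan$F) && is.finite(mx$interaction$F))
  # between-subject F equals a one-way ANOVA on subject means
  sm <- aggregate(pvc ~ subject_id + group, data = sp, FUN = mean)
  expect_equal(mx$F, brute_force_anova(sm$pvc, sm$group)$F, tolerance = 1e-9)
})

test_that("power analysis reproduces the closed form and its monotonicity", {
  # d exactly 1: N = 2 * (1.9600 + 0.8416)^2 ~ 15.70 -> 16
  p1 <- power_analysis(0, 2, 2, 2)
  expect_equal(p1$cohen_d, 1)
  expect_equal(p1$n_exact, 2 * (qnorm(0.975) + qnorm(0.8))^2, tolerance = 1e-12)
  expect_equal(p1$n_per_group, 16L)
  # the default quantiles are the conventional 1.96 and 0.8416
  expect_equal(qnorm(0.975), 1.96, tolerance = 1e-3)
  expect_equal(qnorm(0.80), 0.8416, tolerance = 1e-4)

  expect_error(power_analysis(1, 2, 1, 2), "zero effect")
  expect_error(power_analysis(0, 0, 1, 2), "positive")

  # N non-increasing in the mean difference, non-decreasing in the SDs
  deltas <- seq(0.5, 4, by = 0.5)
  ns <- sapply(deltas, function(d) power_analysis(0, 2, d, 2)$n_exact)
  expect_true(all(diff(ns) < 0))
  sds <- seq(1, 4, by = 0.5)
  ns2 <- sapply(sds, function(s) power_analysis(0, s, 2, s)$n_exact)
  expect_true(all(diff(ns2) > 0))
})

test_that("cohort tables validate their invariants", {
  rec <- toy_records(c(-3, -4), subjects = "S1", groups = "AD",
                     scans = "A", sides = c("L", "L"))
  expect_error(cohort_table(rec), "duplicate")
  rec2 <- toy_records(-3, "S1", "AD", "A", "L")
  rec2$pvc <- -10  # inconsistent with volumes
  expect_error(cohort_table(rec2), "inconsistent")
  rec3 <- toy_records(-3, "S1", "AD", "C", "L")
  expect_error(cohort_table(rec3), "scan")
})
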