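fake_records <- function(n_case, n_control, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%03d", seq_len(n_case + n_control)),
             group = rep(c("case", "control"), c(n_case, n_control)),
             age = runif(n_case + n_control, 7, 14),
             stringsAsFactors = FALSE)
}

test_that("group regression isolates the group effect with age as covariate", {
  rec <- fake_records(30, 30)
  # constant response: zero effect, p = 1, flagged
  r0 <- group_age_regression(rep(5, 60), rec)
  expect_equal(c(r0$estimate, r0$p), c(0, 1))
  expect_equal(r0$note, "constant")
  # response driven purely by age: group effect ~ 0
  r1 <- suppressWarnings(group_age_regression(3 * rec$age, rec))
  expect_lt(abs(r1$estimate), 1e-10)
  # injected group effect recovered (single dataset, strong effect)
  sim <- simulate_cluster_depths(60, 60, 1, depth_effects = -2, noise_sd = 1, seed = 3)
  r2 <- group_age_regression(sim$table[, 1], sim$records)
  expect_lt(abs(r2$estimate + 2), 0.5)
  expect_lt(r2$p, 0.001)
  expect_error(group_age_regression(rnorm(60), rec[1:59, ]), "aligned")
  expect_error(group_age_regression(rnorm(4), fake_records(2, 2)), "3 subjects")
})

test_that("age regression estimates the linear slope", {
  rec <- fake_records(50, 50)
  expect_equal(age_regression(rep(5, 100), rec)$estimate, 0)
  # exact two-point line
  rec2 <- data.frame(group = c("case", "control"), age = c(8, 12))
  expect_equal(age_regression(c(4, 8), rec2)$estimate, 1.0, tolerance = 1e-12)
  set.seed(4)
  y <- 2 * rec$age + rnorm(100, 0, 0.1)
  sl <- age_regression(y, rec)$estimate
  expect_gt(sl, 1.9); expect_lt(sl, 2.1)
})

test_that("BH adjustment follows the step-up rule, including enlarged families", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  expect_equal(bh_adjust(p), c(0.05, 0.05, 0.05, 0.05, 0.2))
  expect_equal(bh_adjust(rep(1, 10)), rep(1, 10))
  set.seed(6)
  for (i in 1:50) {
    pv <- runif(sample(3:40, 1))^sample(1:3, 1)
    fam <- length(pv) + sample(0:10, 1)
    expect_equal(bh_adjust(pv, fam), oracle_bh(pv, fam), tolerance = 1e-12)
  }
  # NAs (skipped tests) keep their place; family covers them
  pna <- c(0.01, NA, 0.04)
  q <- bh_adjust(pna, 3)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(c(0.01, 0.04), 3))
  expect_error(bh_adjust(c(0.1, 0.2), 1), "family_size")
})

test_that("per-cluster tests exclude missing subjects and keep skipped clusters in the family", {
  sim <- simulate_cluster_depths(20, 20, 4, depth_effects = c(2, 0, 0, 0),
                                 noise_sd = 0.4, seed = 8)
  tab <- sim$table
  tab[1:18, 3] <- NA                      # cases nearly absent in cluster 3
  expect_warning(res <- per_cluster_tests(tab, sim$records), "skipped")
  expect_true(res$skipped[3])
  expect_true(is.na(res$q[3]))
  expect_false(any(res$skipped[c(1, 2, 4)]))
  expect_true(res$significant[1])
  expect_gt(res$estimate[1], 0)
  # q-values equal the oracle on the stated family
  ok <- !is.na(res$p)
  expect_equal(res$q[ok], oracle_bh(res$p[ok], 4), tolerance = 1e-12)
  # all-null p-values: nothing significant
  sim0 <- simulate_cluster_depths(20, 20, 5, seed = 9)
  res0 <- per_cluster_tests(sim0$table, sim0$records)
  expect_false(any(res0$significant))
})

test_that("the asymmetry index has the documented endpoints and symmetries", {
  expect_equal(asymmetry_index(2, 2), 0)
  expect_equal(asymmetry_index(0, 3), -1)   # completely right-lateralized
  expect_equal(asymmetry_index(3, 0), +1)   # completely left-lateralized
  set.seed(10)
  L <- runif(200, 0, 5); R <- runif(200, 0, 5)
  ai <- asymmetry_index(L, R)
  expect_true(all(ai >= -1 & ai <= 1))
  expect_equal(asymmetry_index(R, L), -ai)
  expect_true(is.na(asymmetry_index(0, 0)))
})

test_that("AI group tests flag a lateralized case-only deepening", {
  rec <- fake_records(40, 40, seed = 12)
  set.seed(12)
  base <- matrix(rnorm(80 * 3, 5, 0.2), 80, 3)
  L <- base; R <- base + matrix(rnorm(80 * 3, 0, 0.2), 80, 3)
  L[rec$group == "case", 2] <- L[rec$group == "case", 2] + 1.0
  colnames(L) <- colnames(R) <- c("a", "b", "c")
  res <- ai_group_tests(L, R, rec)
  expect_gt(res$estimate[2], 0)
  expect_true(res$significant[2])
  expect_false(res$significant[1] || res$significant[3])
  # identical tables: AI constant zero, nothing significant
  res0 <- ai_group_tests(base, base, rec)
  expect_true(all(res0$p == 1))
  # single-cluster family: q equals p
  res1 <- ai_group_tests(L[, 1, drop = FALSE], R[, 1, drop = FALSE], rec)
  expect_equal(res1$q, res1$p)
})

test_that("hemisphere RM-ANOVA equals the squared paired t and handles degeneracy", {
  rec <- fake_records(10, 25, seed = 14)
  set.seed(14)
  n <- 35
  L <- matrix(rnorm(n * 2, 5, 0.5), n, 2)
  R <- L + matrix(rnorm(n * 2, 0.3, 0.5), n, 2)
  res <- within_group_hemisphere_test(L, R, rec, group = "control")
  ctl <- rec$group == "control"
  for (j in 1:2) {
    t_or <- oracle_paired_t(L[ctl, j], R[ctl, j])
    expect_equal(res$F[j], t_or^2, tolerance = 1e-10)
    p_or <- 2 * pt(-abs(t_or), sum(ctl) - 1)
    expect_equal(res$p[j], p_or, tolerance = 1e-10)
  }
  # identical hemispheres: F = 0, p = 1
  r0 <- within_group_hemisphere_test(L, L, rec, group = "control")
  expect_true(all(r0$F == 0) && all(r0$p == 1))
  # constant nonzero difference: degenerate, p -> 0
  r1 <- within_group_hemisphere_test(L + 1, L, rec, group = "control")
  expect_true(all(r1$degenerate))
  expect_true(all(r1$p == 0))
  # too few pairs: skipped
  Lna <- L; Lna[ctl, 1][-(1:2)] <- NA
  r2 <- within_group_hemisphere_test(Lna, R, rec, group = "control")
  expect_true(r2$skipped[1])
})

test_that("RM-ANOVA detects a consistent hemispheric shift", {
  hits <- 0L
  for (s in 1:25) {
    set.seed(400 + s)
    L <- matrix(rnorm(50, 5, 0.5), 50, 1)
    R <- L + matrix(rnorm(50, 0.3, 0.5), 50, 1)
    rec <- data.frame(group = rep("control", 50), age = runif(50, 7, 14))
    r <- within_group_hemisphere_test(L, R, rec, group = "control")
    if (!is.na(r$p[1]) && r$p[1] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 22L)   # ~ 0.3 / (0.5/sqrt(50)) shift: power well above 90%
})

test_that("subtype comparison contrasts combined vs inattentive within cases", {
  rec <- fake_records(40, 10, seed = 16)
  rec$subtype <- ifelse(rec$group == "case",
                        rep(c("combined", "inattentive"), 20), "none")
  set.seed(16)
  y <- rnorm(50, 10, 1) + 2 * (rec$subtype == "combined")
  r <- subtype_comparison(y, rec)
  expect_gt(r$estimate, 1)
  expect_lt(r$p, 0.01)
  rec2 <- rec; rec2$subtype[rec2$group == "case"] <- "combined"
  expect_error(subtype_comparison(y, rec2), "both subtypes")
  # exchangeable subtypes: estimate near zero on a permuted copy
  set.seed(17)
  rec3 <- rec
  rec3$subtype[rec3$group == "case"] <- sample(rec$subtype[rec$group == "case"])
  y0 <- rnorm(50, 10, 1)
  r0 <- subtype_comparison(y0, rec3)
  expect_lt(abs(r0$estimate), 1.5)
})
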