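# The four published contingency-table p-values jointly pin the convention:
# Yates continuity correction exactly and only for 2x2 tables.
test_that("chi-square reproduces the published nodal-stage p-values", {
  p13 <- chi_square(matrix(c(145, 40, 107, 13), 2, byrow = TRUE))
  expect_equal(signif(p13$p_value, 3), 0.0229)
  p23 <- chi_square(matrix(c(94, 26, 107, 13), 2, byrow = TRUE))
  expect_equal(signif(p23$p_value, 3), 0.0358)
  p3 <- chi_square(matrix(c(145, 40, 94, 26, 107, 13), 3, byrow = TRUE))
  expect_equal(signif(p3$p_value, 3), 0.0361)
  expect_equal(p3$df, 2)
  lymph <- chi_square(matrix(c(41, 138, 26, 91, 13, 98), 3, byrow = TRUE))
  expect_equal(signif(lymph$p_value, 3), 0.0469)
  # the 2x2 values only match with the correction, the 3x2 only without
  expect_false(signif(chi_square(matrix(c(145, 40, 107, 13), 2, byrow = TRUE),
                                 yates_2x2 = FALSE)$p_value, 3) == 0.0229)
})

test_that("chi-square handles degenerate and erroneous tables", {
  prop <- matrix(c(10, 20, 30, 60), 2)  # perfectly proportional
  r <- chi_square(prop, yates_2x2 = FALSE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin", class = "netstrat_test_error")
  expect_error(chi_square(matrix(1:3, 1)), class = "netstrat_test_error")
})

test_that("Yates and uncorrected tests converge as counts scale up", {
  tab <- matrix(c(14, 5, 11, 13), 2)
  d1 <- abs(chi_square(tab)$p_value -
              chi_square(tab, yates_2x2 = FALSE)$p_value)
  d2 <- abs(chi_square(tab * 100)$p_value -
              chi_square(tab * 100, yates_2x2 = FALSE)$p_value)
  expect_lt(d2, d1 / 10)
})

test_that("Kruskal-Wallis H matches a permutation-null Monte Carlo", {
  vals <- c(-2, 0, 3, -2, 0, 1, 2, 1, 5, 1, 3, 4, 1, 0, 6)  # ties present
  grp <- rep(c("a", "b", "c"), each = 5)
  res <- kruskal_wallis(vals, grp)
  H <- res$statistic
  set.seed(123)
  perm <- replicate(10000, {
    suppressWarnings(kruskal.test(vals, factor(sample(grp)))$statistic)
  })
  expect_lt(abs(mean(perm >= H - 1e-12) - res$p_value), 0.01)
})

test_that("two-group Kruskal-Wallis equals the squared standardized rank sum", {
  set.seed(8)
  x <- rnorm(9); y <- rnorm(7) + 0.5  # continuous, no ties
  vals <- c(x, y); grp <- rep(1:2, c(9, 7))
  H <- kruskal_wallis(vals, grp)$statistic
  rk <- rank(vals)
  W <- sum(rk[grp == 1])
  n <- 16; n1 <- 9; n2 <- 7
  z <- (W - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-12)
})

test_that("Kruskal-Wallis flags degenerate constant input", {
  r <- kruskal_wallis(rep(5, 9), rep(1:3, 3))
  expect_true(r$degenerate)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # identical multisets across groups give statistic 0
  r2 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum approximation tracks exact enumeration", {
  x <- c(4.6, -2.4, -1.4, -0.8, -1.9)
  y <- c(0.6, 4.0, 2.3, 2.8, 6.9)
  res <- wilcoxon_rank_sum(x, y)
  # exact two-sided p by full enumeration of the 252 group assignments
  pool <- c(x, y)
  rk <- rank(pool)
  obs <- sum(rk[1:5]) - 15  # Mann-Whitney U of x
  combs <- utils::combn(10, 5)
  us <- apply(combs, 2, function(ix) sum(rk[ix]) - 15)
  exact <- mean(abs(us - 12.5) >= abs(obs - 12.5) - 1e-12)
  expect_lt(abs(res$p_value - exact), 0.005)
  # equal multisets -> p essentially 1
  expect_gte(wilcoxon_rank_sum(x, x)$p_value, 0.99)
  # complete separation -> tiny p
  expect_lt(wilcoxon_rank_sum(1:10, 101:110)$p_value, 1e-3)
})

test_that("Kaplan-Meier and log-rank match a hand-worked 6-subject example", {
  # group A: deaths at 1, 3; censored at 5.  group B: death at 2; censored 4, 6
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 0, 0)
  grp <- rep(c("A", "B"), each = 3)
  res <- km_logrank(time, event, grp)
  a <- res$curves[res$curves$group == "A", ]
  # product-limit by hand: S(1)=2/3, S(3)=1/3
  expect_equal(a$survival[a$time == 1], 2 / 3)
  expect_equal(a$survival[a$time == 3], 1 / 3)
  b <- res$curves[res$curves$group == "B", ]
  expect_equal(b$survival[b$time == 2], 2 / 3)
  # log-rank by hand over event times 1, 2, 3:
  # t=1: O_A=1 E_A=3/6;  t=2: O_A=0 E_A=2/5;  t=3: O_A=1 E_A=2/4
  # U = sum(O-E) = 0.6; Var = 1*(3*3)/36 + 1*(2*3)/25 + 1*(2*2)/16 = 0.74
  U <- 1 - 3 / 6 + 0 - 2 / 5 + 1 - 2 / 4
  V <- (3 * 3) / 36 + (2 * 3) / 25 + (2 * 2) / 16
  expect_equal(res$test$statistic, U^2 / V, tolerance = 1e-10)
  expect_equal(res$test$p_value,
               pchisq(U^2 / V, 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("log-rank degenerates gracefully", {
  # no events anywhere
  r <- km_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0), rep(1:2, 2))
  expect_true(r$test$degenerate)
  expect_equal(r$test$p_value, 1)
  expect_true(all(r$curves$survival == 1))
  # identical groups (duplicated data) -> p = 1
  t2 <- c(1, 2, 3, 1, 2, 3); e2 <- c(1, 0, 1, 1, 0, 1)
  r2 <- km_logrank(t2, e2, rep(1:2, each = 3))
  expect_equal(r2$test$p_value, 1, tolerance = 1e-12)
})

test_that("association battery reproduces the published N-stage p-value", {
  # reconstruct patient-level rows from the published per-subtype counts
  lab <- rep(1:3, c(145 + 40, 94 + 26, 107 + 13))
  path_n <- c(rep(c("N0", "N1"), c(145, 40)),
              rep(c("N0", "N1"), c(94, 26)),
              rep(c("N0", "N1"), c(107, 13)))
  cl <- data.frame(patient_id = paste0("p", seq_along(lab)),
                   path_n = path_n,
                   followup_days = 100, event = 0,
                   stringsAsFactors = FALSE)
  names(lab) <- cl$patient_id
  bat <- association_battery(lab, cl)
  expect_equal(signif(bat$p_values["path_n", 1], 3), 0.0361)
})

test_that("battery is null-calibrated on subtype-independent clinical data", {
  set.seed(31)
  ps <- c()
  for (i in 1:20) {
    lab <- sample(1:3, 120, TRUE)
    cl <- generate_clinical(lab, clinical_effects(3, null = TRUE),
                            seed = 1000 + i)
    lab <- stats::setNames(lab, cl$patient_id)
    bat <- association_battery(lab, cl)
    ps <- c(ps, bat$p_values[, 1])
  }
  ps <- ps[!is.na(ps)]
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("battery survives a single shared label", {
  cl <- generate_clinical(rep(1, 30), clinical_effects(1), seed = 2)
  lab <- stats::setNames(rep(1L, 30), cl$patient_id)
  bat <- association_battery(lab, cl)
  expect_true(all(is.na(bat$p_values) |
                    vapply(bat$tests[[1]], function(t)
                      isTRUE(t$degenerate), logical(1))))
})

test_that("tests are invariant to patient reordering", {
  set.seed(17)
  vals <- rnorm(30); grp <- sample(1:3, 30, TRUE)
  o <- sample(30)
  expect_equal(kruskal_wallis(vals, grp)$p_value,
               kruskal_wallis(vals[o], grp[o])$p_value)
  tab <- table(grp, vals > 0)
  expect_equal(chi_square(tab)$p_value, chi_square(tab[c(2, 1, 3), ])$p_value)
})
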