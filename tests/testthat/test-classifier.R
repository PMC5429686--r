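# Well-separated 3-class Gaussian toy problem.
toy_classes <- function(n_per = 10, p = 12, sep = 4, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(0:2, function(k) {
    mu <- rep(0, p); mu[k * 4 + 1:4] <- sep
    matrix(rnorm(n_per * p), n_per, p) + rep(mu, each = n_per)
  }))
  dimnames(X) <- list(paste0("s", seq_len(3 * n_per)), paste0("g", 1:p))
  list(X = X, y = rep(c("A", "B", "C"), each = n_per))
}

test_that("overwhelming penalty shrinks every gene coefficient to zero", {
  tc <- toy_classes()
  fit <- fit_elastic_net(tc$X, tc$y, alpha = 0.5, lambda = 1e6)
  expect_true(all(fit$coefficients == 0))
  pred <- predict(fit, tc$X)
  expect_equal(length(unique(pred)), 1)  # majority/intercept-only rule
  bio <- extract_biomarkers(fit)
  expect_true(all(lengths(bio$per_class) == 0))
  expect_equal(bio$union_size, 0)
})

test_that("separable classes are fit perfectly at small lambda", {
  tc <- toy_classes()
  fit <- fit_elastic_net(tc$X, tc$y, alpha = 0.9, lambda = 0.01)
  expect_equal(unname(predict(fit, tc$X)), tc$y)
  expect_error(fit_elastic_net(tc$X[1:11, ], tc$y[1:11], 0.5, 1),
               "fewer than 2", class = "netstrat_fit_error")
})

test_that("biomarker extraction is exact set algebra on known supports", {
  beta <- matrix(0, 6, 3, dimnames = list(paste0("g", 1:6), c("A", "B", "C")))
  beta[c(1, 2, 3), "A"] <- 1
  beta[c(3, 4), "B"] <- -2
  beta[c(1, 3, 5), "C"] <- 0.5
  bio <- extract_biomarkers(list(coefficients = beta))
  expect_identical(bio$per_class$A, c("g1", "g2", "g3"))
  expect_equal(bio$union_size, 5)
  ov <- bio$pairwise
  expect_equal(ov$overlap[ov$class_a == "A" & ov$class_b == "B"], 1)
  expect_equal(ov$overlap[ov$class_a == "A" & ov$class_b == "C"], 2)
  expect_equal(ov$overlap[ov$class_a == "B" & ov$class_b == "C"], 1)
  # identical supports: overlaps equal the list length
  beta2 <- beta; beta2[] <- 0; beta2[1:2, ] <- 1
  bio2 <- extract_biomarkers(list(coefficients = beta2))
  expect_true(all(bio2$pairwise$overlap == 2))
})

test_that("support size does not grow when lambda increases tenfold", {
  tc <- toy_classes(n_per = 12, sep = 2)
  n1 <- sum(fit_elastic_net(tc$X, tc$y, 1, 0.02)$coefficients != 0)
  n2 <- sum(fit_elastic_net(tc$X, tc$y, 1, 0.2)$coefficients != 0)
  expect_lte(n2, n1)
})

test_that("jackknife achieves zero error on separable data and tunes sanely", {
  tc <- toy_classes()
  tune <- jackknife_tune(tc$X, tc$y, alpha_grid = c(0.5, 1), nlambda = 12)
  expect_equal(tune$error, 0)
  expect_equal(tune$accuracy, 1)
  # order invariance
  o <- sample(nrow(tc$X))
  tune2 <- jackknife_tune(tc$X[o, ], tc$y[o], alpha_grid = c(0.5, 1),
                          nlambda = 12)
  expect_equal(tune2$error, tune$error)
  expect_error(jackknife_tune(tc$X, tc$y, alpha_grid = numeric(0)),
               class = "netstrat_config_error")
})

test_that("leave-one-out loop equals an independent re-implementation", {
  tc <- toy_classes(n_per = 4, p = 12, sep = 1.5, seed = 7)
  path <- c(0.5, 0.1, 0.02)
  tune <- jackknife_tune(tc$X, tc$y, alpha_grid = 0.8, lambda_path = path)
  # independent loop written from the definition
  errs <- sapply(path, function(lam) {
    wrong <- 0
    for (i in seq_len(nrow(tc$X))) {
      fit <- glmnet::glmnet(tc$X[-i, ], factor(tc$y[-i]),
                            family = "multinomial", alpha = 0.8,
                            lambda = path)
      pr <- predict(fit, newx = tc$X[i, , drop = FALSE], s = lam,
                    type = "class")
      if (as.character(pr) != tc$y[i]) wrong <- wrong + 1
    }
    wrong / nrow(tc$X)
  })
  tab <- tune$error_table
  expect_equal(tab$error[match(path, tab$lambda)], unname(errs))
  expect_equal(tune$error, min(errs))
  # tie-break prefers the larger lambda
  best <- tab[tab$error == tune$error, ]
  expect_equal(tune$lambda, max(best$lambda))
})

test_that("null-feature data yields chance-level jackknife error", {
  set.seed(19)
  errs <- vapply(1:3, function(i) {
    X <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(paste0("s", 1:40), paste0("g", 1:8)))
    y <- rep(c("A", "B"), 20)
    jackknife_tune(X, y, alpha_grid = 1, nlambda = 8)$error
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.15)
})

test_that("ridge-limit coefficients match a direct penalized optimizer", {
  set.seed(23)
  n <- 24; p <- 3
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- rbinom(n, 1, plogis(X %*% c(1, -1, 0.5)))
  lam <- 0.1
  fit <- glmnet::glmnet(X, factor(y), family = "binomial", alpha = 0,
                        lambda = lam, standardize = FALSE, thresh = 1e-14)
  # direct minimization of -loglik/n + lam/2 * ||beta||^2
  obj <- function(par) {
    eta <- par[1] + X %*% par[-1]
    -mean(y * eta - log1p(exp(eta))) + lam / 2 * sum(par[-1]^2)
  }
  opt <- optim(rep(0, p + 1), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_lt(max(abs(opt$par - c(fit$a0, as.numeric(fit$beta)))), 1e-4)
})

test_that("top-n sweep is deterministic with one row per requested n", {
  co <- generate_cohort(small_spec(seed = 4, n_patients = 36L))
  sm <- smooth_cohort(intersect_with_network(co$mutations,
                                             co$network)$matrix, co$network)
  labs <- co$true_labels[rownames(sm)]
  sw <- top_n_sweep(sm, labs, n_values = c(30, 60, 60),
                    alpha_grid = 1, nlambda = 8)
  expect_equal(sw$n_genes, c(30, 60, 60))
  expect_equal(sw$accuracy[2], sw$accuracy[3])
  expect_error(top_n_sweep(sm, labs, n_values = 1e6),
               class = "netstrat_config_error")
})

test_that("strong-signal synthetic cohorts classify accurately at any n", {
  co <- generate_cohort(small_spec(seed = 6, n_patients = 60L,
                                   inter_edge_prob = 0.005,
                                   drivers_per_subtype = 15L,
                                   driver_mut_prob = 0.9))
  sm <- smooth_cohort(intersect_with_network(co$mutations,
                                             co$network)$matrix, co$network)
  labs <- co$true_labels[rownames(sm)]
  sw <- top_n_sweep(sm, labs, n_values = c(40, 80), alpha_grid = c(0.5, 1),
                    nlambda = 12)
  expect_true(all(sw$accuracy >= 0.9))
})
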