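test_that("cox_fit populates a coherent fit object", {
  d <- sim_exp_cohort(n = 150, beta = 0.5, seed = 2)
  fit <- cox_fit(d$clin, d$x)
  expect_s3_class(fit, "cox_fit")
  expect_equal(unname(fit$hr), exp(unname(fit$beta)), tolerance = 1e-12)
  expect_true(fit$ci95[1, "lower"] <= fit$hr && fit$hr <= fit$ci95[1, "upper"])
  expect_equal(fit$aic, -2 * fit$loglik + 2, tolerance = 1e-12)
  # matches the reference survival-package fit on the same data
  ref <- survival::coxph(survival::Surv(d$clin$time, d$clin$event) ~ d$x)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-8)
})

test_that("null covariates stay near HR 1 across seeds", {
  hrs <- ps <- numeric(10)
  for (seed in 1:10) {
    d <- sim_exp_cohort(n = 500, beta = 0, seed = seed)
    f <- cox_fit(d$clin, d$x)
    hrs[seed] <- f$hr; ps[seed] <- f$p_global
  }
  expect_gte(sum(hrs > 0.85 & hrs < 1.18 & ps > 0.05), 8)
})

test_that("the CI covers a true rate ratio of 2 at nominal frequency", {
  covered <- vapply(1:200, function(seed) {
    d <- sim_exp_cohort(n = 400, beta = log(2), seed = seed, binary = TRUE)
    f <- cox_fit(d$clin, d$x)
    f$ci95[1, "lower"] <= 2 && 2 <= f$ci95[1, "upper"]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("degenerate survival inputs are refused", {
  d <- sim_exp_cohort(n = 50, seed = 3)
  expect_error(cox_fit(d$clin, rep(1, 50)), "constant|information")
  no_events <- clinical_table(d$clin$sample_id, d$clin$time, rep(0L, 50))
  expect_error(cox_fit(no_events, d$x), "2 events")
})

test_that("Efron and Breslow agree exactly when there are no ties", {
  d <- sim_exp_cohort(n = 120, beta = 0.4, seed = 5)
  stopifnot(!anyDuplicated(d$clin$time[d$clin$event == 1]))
  fe <- cox_fit(d$clin, d$x, ties = "efron")
  fb <- cox_fit(d$clin, d$x, ties = "breslow")
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-12)
  expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
})

test_that("rescaling a covariate rescales beta and leaves p untouched", {
  d <- sim_exp_cohort(n = 150, beta = 0.6, seed = 6)
  f1 <- cox_fit(d$clin, d$x)
  f2 <- cox_fit(d$clin, d$x * 10)
  expect_equal(unname(f2$beta), unname(f1$beta) / 10, tolerance = 1e-6)
  expect_equal(f2$p_global, f1$p_global, tolerance = 1e-8)
  expect_equal(unname(f2$p), unname(f1$p), tolerance = 1e-6)
})

test_that("log-rank statistic matches the hand-computed 6-subject table", {
  clin <- clinical_table(sprintf("s%d", 1:6),
                         time = c(1, 3, 5, 2, 4, 6),
                         event = c(1, 1, 0, 1, 1, 1))
  groups <- setNames(rep(c("g1", "g2"), each = 3), clin$sample_id)
  res <- logrank_test(clin, groups)
  oracle <- logrank_oracle(clin$time, clin$event, unname(groups == "g1"))
  expect_equal(res$statistic, oracle, tolerance = 1e-10)
  expect_equal(res$p, pchisq(oracle, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("identical duplicated groups give a zero log-rank statistic", {
  d <- sim_exp_cohort(n = 40, seed = 7)
  clin2 <- clinical_table(c(d$clin$sample_id, paste0(d$clin$sample_id, "_b")),
                          rep(d$clin$time, 2), rep(d$clin$event, 2))
  groups <- rep(c("a", "b"), each = 40)
  res <- logrank_test(clin2, groups)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)
  expect_error(logrank_test(d$clin, rep("a", 40)), "2 groups")
})

test_that("a 3x hazard ratio is detected by the log-rank test across seeds", {
  ps <- vapply(1:10, function(seed) {
    d <- sim_exp_cohort(n = 300, beta = log(3), seed = seed, binary = TRUE)
    logrank_test(d$clin, ifelse(d$x > 0, "hi", "lo"))$p
  }, numeric(1))
  expect_gte(sum(ps < 0.01), 9)
})

test_that("the CV cutpoint recovers a planted score split", {
  agree <- vapply(1:5, function(seed) {
    withr::with_seed(seed, {
      n <- 200
      pheno <- rbinom(n, 1, 0.5)
      score <- pheno + rnorm(n, sd = 0.2)
      t_event <- rexp(n, 0.01 * exp(-1.2 * pheno))
      cens <- runif(n, 0, quantile(t_event, 0.8) * 2)
    })
    clin <- clinical_table(sprintf("s%03d", 1:n), pmin(t_event, cens),
                           as.integer(t_event <= cens))
    cp <- cv_optimal_cutpoint(clin, setNames(score, clin$sample_id), seed = seed)
    mean((cp$groups == "high") == (pheno == 1))
  }, numeric(1))
  expect_true(all(agree >= 0.9))
})

test_that("the CV cutpoint is deterministic and rejects constant scores", {
  d <- sim_exp_cohort(n = 100, beta = 1, seed = 9)
  a <- cv_optimal_cutpoint(d$clin, d$x, seed = 3)
  b <- cv_optimal_cutpoint(d$clin, d$x, seed = 3)
  expect_identical(a$cutpoint, b$cutpoint)
  expect_identical(a$groups, b$groups)
  expect_true(a$cutpoint %in% a$cv$candidates)
  expect_error(cv_optimal_cutpoint(d$clin, setNames(rep(1, 100),
                                                    d$clin$sample_id)),
               "constant")
  expect_error(cv_optimal_cutpoint(d$clin[1:20, ], d$x[1:20]), "5-fold|at least")
})

test_that("combined scores are sums of z-scores with zero mean", {
  withr::with_seed(4, {
    vals <- matrix(rnorm(30 * 40), nrow = 30,
                   dimnames = list(sprintf("s%02d", 1:30), sprintf("f%02d", 1:40)))
  })
  m <- expr_matrix(vals, "coding")
  sets <- list(A = gene_set("A", colnames(vals)[1:5]),
               B = gene_set("B", colnames(vals)[6:10]))
  tab <- score_signatures(m, sets)
  comb <- combined_score(tab, "A", "B")
  expect_equal(mean(comb), 0, tolerance = 1e-12)
  double <- combined_score(tab, "A", "A")
  expect_equal(double, 2 * setNames(tab$es_scaled[tab$signature == "A"],
                                    tab$sample_id[tab$signature == "A"]),
               tolerance = 1e-12)
  expect_error(combined_score(tab, "A", "missing"), "not found")
})

test_that("AIC comparison is antisymmetric and guards cohort identity", {
  d <- sim_exp_cohort(n = 150, beta = 0.5, seed = 11)
  withr::with_seed(12, x2 <- d$x + rnorm(150, sd = 0.5))
  fa <- cox_fit(d$clin, d$x)
  fb <- cox_fit(d$clin, setNames(x2, names(d$x)))
  expect_equal(compare_aic(fa, fa), 0)
  expect_equal(compare_aic(fa, fb), -compare_aic(fb, fa), tolerance = 1e-12)
  other <- sim_exp_cohort(n = 80, beta = 0.5, seed = 13)
  fo <- cox_fit(other$clin, other$x)
  expect_error(compare_aic(fa, fo), "mismatched")
})

test_that("forest tables flag planted hazard directions across cohorts", {
  flags <- vapply(1:10, function(seed) {
    fits <- lapply(c(enabled = -0.9, neutral = 0, disabled = 0.9),
                   function(beta) {
                     d <- sim_exp_cohort(n = 250, beta = beta,
                                         seed = seed * 100 + round(beta * 10))
                     cox_fit(d$clin, d$x)
                   })
    ft <- forest_table(fits)
    all(ft$class == c("enabled", "neutral", "disabled"))
  }, logical(1))
  expect_gte(sum(flags), 8)
})

test_that("the fitted ICR hazard direction matches the planted sign", {
  ok <- vapply(1:10, function(seed) {
    co <- small_cohort(seed = seed, hazard_coef = -0.7)
    icr_score <- scale(rowMeans(
      co$expression$values[, co$truth$icr_genes, drop = FALSE]))[, 1]
    fit <- cox_fit(co$clinical, setNames(icr_score, co$clinical$sample_id))
    sign(fit$beta) == sign(co$truth$true_hazard_coef) &&
      (fit$ci95[1, "lower"] <= exp(-0.7) && exp(-0.7) <= fit$ci95[1, "upper"])
  }, logical(1))
  expect_gte(sum(ok), 8)
})
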