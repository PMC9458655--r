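test_that("PRS standardization is exact and validates input", {
  d <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "rs1"))
  w <- tibble::tibble(variant_id = "rs1", effect_allele = "A", weight = 1)
  z <- compute_prs(d, w)
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  flat <- matrix(1, nrow = 4, ncol = 1, dimnames = list(NULL, "rs1"))
  expect_error(compute_prs(flat, w), "zero variance")
  expect_error(compute_prs(d, dplyr::bind_rows(w, w)), "duplicate")
  bad <- d; bad[1, 1] <- 3
  expect_error(compute_prs(bad, w), "0, 2")
})

test_that("PRS is invariant to consistent allele flips", {
  set.seed(40)
  d <- matrix(rbinom(300, 2, 0.4), ncol = 3,
              dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  w <- tibble::tibble(variant_id = c("rs1", "rs2", "rs3"),
                      effect_allele = c("A", "C", "G"),
                      weight = c(0.2, -0.1, 0.4))
  z1 <- compute_prs(d, w)
  # flip rs2: count the other allele; resolvable through other_alleles
  d2 <- d
  d2[, "rs2"] <- 2 - d2[, "rs2"]
  z2 <- compute_prs(d2, w,
                    counted_alleles = c(rs1 = "A", rs2 = "T", rs3 = "G"),
                    other_alleles = c(rs1 = "G", rs2 = "T", rs3 = "A"))
  expect_equal(z1, z2, tolerance = 1e-12)
  expect_error(
    compute_prs(d2, w, counted_alleles = c(rs1 = "A", rs2 = "X", rs3 = "G"),
                other_alleles = c(rs1 = "G", rs2 = "T", rs3 = "A")),
    "mismatch"
  )
})

test_that("PRS-risk logistic link recovers the per-SD odds ratio", {
  # generator cohort with OR 1.33 per PRS SD on disease liability
  set.seed(41)
  n <- 6000
  d <- matrix(rbinom(n * 10, 2, 0.3), ncol = 10,
              dimnames = list(NULL, paste0("rs", 1:10)))
  w <- tibble::tibble(variant_id = paste0("rs", 1:10),
                      effect_allele = rep("A", 10),
                      weight = runif(10, 0.02, 0.1))
  z <- compute_prs(d, w)
  p <- plogis(-0.5 + log(1.33) * z)
  y <- rbinom(n, 1, p)
  fit <- glm(y ~ z, family = binomial())
  ci <- confint.default(fit)["z", ]
  expect_true(log(1.33) >= ci[1] && log(1.33) <= ci[2])
})

test_that("IVW consensus, validation and recovery", {
  ins <- tibble::tibble(beta_exposure = c(0.1, 0.2),
                        se_exposure = 0.01,
                        beta_outcome = c(0.2, 0.4), se_outcome = 0.05)
  expect_equal(mr_ivw(ins)$estimate, 2, tolerance = 1e-12)
  expect_error(mr_ivw(ins[1, ]), "at least 2")
  ins2 <- emit_instruments(20, 0.5, seed = 42)
  fit <- mr_ivw(ins2)
  expect_lt(abs(fit$estimate - 0.5), 3 * fit$se)
})

test_that("Egger recovers an exact affine relation and pleiotropy", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  ins <- tibble::tibble(beta_exposure = bx, se_exposure = 0.01,
                        beta_outcome = 2 * bx + 0.1, se_outcome = 0.05)
  fit <- mr_egger(ins)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-9)
  expect_error(mr_egger(ins[1:2, ]), "at least 3")
  # constant directional pleiotropy alpha shows up in the intercept
  set.seed(43)
  ins2 <- emit_instruments(30, 0.5,
                           pleiotropy_spec = list(indices = 1:30,
                                                  alpha = 0.15),
                           seed = 44)
  fit2 <- mr_egger(ins2)
  expect_lt(abs(fit2$intercept - 0.15), 3 * fit2$se_intercept)
  # pleiotropy-free intercept is null
  ins3 <- emit_instruments(30, 0.5, seed = 45)
  fit3 <- mr_egger(ins3)
  expect_lt(abs(fit3$intercept), 3 * fit3$se_intercept)
})

test_that("median estimators: exact small cases and robustness", {
  ins <- tibble::tibble(beta_exposure = c(1, 1, 1), se_exposure = 0.01,
                        beta_outcome = c(1, 2, 3), se_outcome = c(1, 1, 1))
  expect_equal(mr_median(ins, weighted = FALSE, n_boot = 100)$estimate, 2)
  # weights concentrated on one ratio pull the weighted median to it
  ins_w <- tibble::tibble(beta_exposure = c(1, 1, 10), se_exposure = 0.01,
                          beta_outcome = c(1, 2, 30),
                          se_outcome = c(1, 1, 0.1))
  expect_equal(mr_median(ins_w, weighted = TRUE, n_boot = 100)$estimate, 3,
               tolerance = 0.05)
  # one gross outlier among 9 valid instruments barely moves the estimate
  set.seed(46)
  ins_r <- emit_instruments(10, 1, seed = 47)
  ins_r$beta_outcome[1] <- ins_r$beta_outcome[1] + 5
  fit <- mr_median(ins_r, weighted = TRUE, n_boot = 2000)
  expect_lt(abs(fit$estimate - 1), 3 * fit$se)
})

test_that("maximum likelihood equals IVW on homogeneous instruments", {
  bx <- c(0.1, 0.15, 0.2, 0.25)
  ins <- tibble::tibble(beta_exposure = bx, se_exposure = 0.01,
                        beta_outcome = 1.7 * bx, se_outcome = 0.05)
  ml <- mr_maxlik(ins)
  ivw <- mr_ivw(ins)
  expect_lt(abs(ml$estimate - ivw$estimate), 1e-6)
  expect_equal(ml$estimate, 1.7, tolerance = 1e-6)
  # two instruments in exact agreement
  ins2 <- ins[1:2, ]
  expect_equal(mr_maxlik(ins2)$estimate, 1.7, tolerance = 1e-6)
  # simulation recovery
  ins3 <- emit_instruments(20, 1, seed = 48)
  fit3 <- mr_maxlik(ins3)
  expect_lt(abs(fit3$estimate - 1), 3 * fit3$se)
})

test_that("pleiotropy filter flags large-alpha variants and validates n", {
  ins <- emit_instruments(19, 0.5,
                          pleiotropy_spec = list(indices = 3L, alpha = 0.8),
                          seed = 49)
  res <- pleiotropy_filter(ins)
  expect_true("rs00003" %in% res$removed$variant_id)
  expect_true(all(c("q_contribution", "q_fdr") %in% names(res$kept)))
  expect_error(pleiotropy_filter(ins[1:3, ]), "at least 4")
  # null calibration: few removals on average without injected pleiotropy
  removed <- vapply(1:40, function(i) {
    nrow(pleiotropy_filter(emit_instruments(15, 0.5, seed = 500 + i))$removed)
  }, double(1))
  expect_lte(mean(removed), 0.2 * 15)
})

test_that("liability transformation is linear and matches the Lee formula", {
  expect_equal(liability_h2(0, 0.1667, 5.69e-5), 0)
  # linearity in observed heritability
  h <- liability_h2(1, 0.1667, 5.69e-5)
  expect_equal(liability_h2(0.25, 0.1667, 5.69e-5), 0.25 * h)
  # independent reimplementation of the transformation
  lee <- function(h2, P, K) {
    z <- exp(-qnorm(1 - K)^2 / 2) / sqrt(2 * pi)
    h2 * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  }
  expect_equal(liability_h2(0.3, 0.1667, 5.69e-5), lee(0.3, 0.1667, 5.69e-5),
               tolerance = 1e-12)
  # K = P collapses to the K(1-K)/z^2 factor
  K <- 0.2
  z <- dnorm(qnorm(1 - K))
  expect_equal(liability_h2(0.4, K, K), 0.4 * K * (1 - K) / z^2,
               tolerance = 1e-12)
  expect_error(liability_h2(0.3, 0, 0.1), "probability")
})

test_that("MR report table carries odds-ratio scale output", {
  ins <- emit_instruments(19, 0.5,
                          pleiotropy_spec = list(indices = 1:5, alpha = 0.5),
                          seed = 50)
  suite <- mr_suite(ins, prune = TRUE, n_boot = 500)
  expect_setequal(suite$table$method,
                  c("ivw", "egger", "simple_median", "weighted_median",
                    "maximum_likelihood"))
  expect_true(all(is.finite(suite$table$or)))
  expect_true(all(suite$table$or_lower < suite$table$or))
  expect_gte(nrow(suite$removed_variants), 1)
})
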