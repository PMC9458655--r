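#' Standardized polygenic score from dosages and per-allele weights
#'
#' Raw score is the weighted sum of effect-allele dosages; the cohort
#' score is standardized to mean 0 and SD 1 (population SD, i.e.
#' denominator n).
#'
#' @param dosages numeric matrix, samples x variants, entries in `[0, 2]`;
#'   column names are variant ids.
#' @param weights tibble (variant_id, effect_allele, weight).
#' @param counted_alleles optional named character vector giving, per
#'   variant, which allele the dosage counts. Variants counted on the
#'   non-effect allele are flipped (dosage -> 2 - dosage) when
#'   `other_alleles` resolves the flip; an unresolvable mismatch errors.
#' @param other_alleles optional named character vector of the
#'   non-effect allele per variant in the weights source.
#' @return numeric vector of z-scored PRS values, one per sample.
#' @export
compute_prs <- function(dosages, weights, counted_alleles = NULL,
                        other_alleles = NULL) {
  if (anyDuplicated(weights$variant_id)) {
    stop("duplicate variant_id in weights", call. = FALSE)
  }
  common <- intersect(colnames(dosages), weights$variant_id)
  if (!length(common)) stop("no overlapping variants", call. = FALSE)
  d <- dosages[, common, drop = FALSE]
  if (any(d < 0 | d > 2)) stop("dosages must lie in [0, 2]", call. = FALSE)
  w <- weights$weight[match(common, weights$variant_id)]
  if (!is.null(counted_alleles)) {
    ea <- weights$effect_allele[match(common, weights$variant_id)]
    ca <- counted_alleles[common]
    mism <- which(ca != ea)
    for (j in mism) {
      oa <- if (!is.null(other_alleles)) other_alleles[common[j]]
            else NA_character_
      if (!is.na(oa) && identical(unname(ca[j]), unname(oa))) {
        d[, j] <- 2 - d[, j]
      } else {
        stop("allele mismatch for ", common[j],
             " cannot be resolved by flipping", call. = FALSE)
      }
    }
  }
  raw <- as.numeric(d %*% w)
  n <- length(raw)
  s <- sd(raw) * sqrt((n - 1) / n)
  if (!is.finite(s) || s == 0) {
    stop("zero variance in raw scores; cannot standardize", call. = FALSE)
  }
  (raw - mean(raw)) / s
}

check_instruments <- function(instruments, min_n) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(need %in% names(instruments)))
  if (nrow(instruments) < min_n) {
    stop("at least ", min_n, " instruments required", call. = FALSE)
  }
  if (any(instruments$se_exposure <= 0) || any(instruments$se_outcome <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  instruments
}

#' Inverse-variance-weighted Mendelian randomization estimate
#'
#' theta = sum(bX bY / sY^2) / sum(bX^2 / sY^2), with fixed-effect
#' SE = sqrt(1 / sum(bX^2 / sY^2)). When Cochran's Q exceeds its degrees
#' of freedom the SE is inflated multiplicatively by sqrt(Q / (n - 1))
#' (multiplicative random-effects model); the model used is recorded.
#'
#' @param instruments tibble with beta_exposure, se_exposure,
#'   beta_outcome, se_outcome.
#' @return tibble (estimate, se, p_value, q_statistic, model).
#' @export
mr_ivw <- function(instruments) {
  instruments <- check_instruments(instruments, 2L)
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  theta <- sum(bx * by * w) / sum(bx^2 * w)
  se_fixed <- sqrt(1 / sum(bx^2 * w))
  q <- sum(w * (by - theta * bx)^2)
  n <- length(bx)
  infl <- max(1, sqrt(q / (n - 1)))
  model <- if (infl > 1) "multiplicative_random_effects" else "fixed_effect"
  se <- se_fixed * infl
  tibble(estimate = theta, se = se,
         p_value = 2 * pnorm(-abs(theta / se)),
         q_statistic = q, model = model)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with an
#' intercept (weights 1 / se_outcome^2), after orienting instruments so
#' all exposure effects are nonnegative. A nonzero intercept estimates
#' directional pleiotropy.
#'
#' @inheritParams mr_ivw
#' @return tibble (slope, se_slope, p_slope, intercept, se_intercept,
#'   p_intercept).
#' @export
mr_egger <- function(instruments) {
  instruments <- check_instruments(instruments, 3L)
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  cf <- coef(fit)
  # summary-statistic regression: residual dispersion is floored at 1 so
  # SEs never shrink below what the outcome SEs alone imply
  s2 <- summary(fit)$sigma^2
  vc <- vcov(fit) / s2 * max(s2, 1)
  se_int <- sqrt(vc[1, 1])
  se_slope <- sqrt(vc[2, 2])
  tibble(
    slope = unname(cf[2]), se_slope = se_slope,
    p_slope = 2 * pnorm(-abs(cf[2] / se_slope)),
    intercept = unname(cf[1]), se_intercept = se_int,
    p_intercept = 2 * pnorm(-abs(cf[1] / se_int))
  )
}

weighted_quantile <- function(x, w, prob = 0.5) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) - 0.5 * w
  cw <- cw / sum(w)
  if (prob <= cw[1]) return(x[1])
  if (prob >= cw[length(cw)]) return(x[length(x)])
  approx(cw, x, xout = prob, ties = "ordered")$y
}

#' Median-based Mendelian randomization estimate
#'
#' Simple: median of per-variant Wald ratios. Weighted: weighted 50th
#' percentile with weights bX^2 / sY^2 (inverse variance of the ratio,
#' first order). The SE comes from a seeded parametric bootstrap that
#' redraws summary statistics from their sampling distributions.
#'
#' @inheritParams mr_ivw
#' @param weighted logical; weighted or simple median.
#' @param n_boot bootstrap draws for the SE.
#' @param boot_seed bootstrap RNG seed.
#' @return tibble (estimate, se, p_value).
#' @export
mr_median <- function(instruments, weighted = TRUE, n_boot = 10000L,
                      boot_seed = 20260921L) {
  instruments <- check_instruments(instruments, 3L)
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  est_fun <- function(bx_i, by_i) {
    r <- by_i / bx_i
    if (weighted) weighted_quantile(r, bx_i^2 / sy^2) else median(r)
  }
  est <- est_fun(bx, by)
  set.seed(as.integer(boot_seed))
  n <- length(bx)
  boots <- vapply(seq_len(n_boot), function(b) {
    est_fun(rnorm(n, bx, sx), rnorm(n, by, sy))
  }, double(1))
  se <- sd(boots)
  tibble(estimate = est, se = se, p_value = 2 * pnorm(-abs(est / se)))
}

#' Maximum-likelihood Mendelian randomization estimate
#'
#' Maximizes the joint normal likelihood of the observed exposure and
#' outcome effects over the causal effect theta and the true exposure
#' effects (one nuisance parameter per variant). The SE comes from the
#' observed information. With homogeneous instruments the estimate
#' coincides with IVW.
#'
#' @inheritParams mr_ivw
#' @return tibble (estimate, se, p_value, converged).
#' @export
mr_maxlik <- function(instruments) {
  instruments <- check_instruments(instruments, 2L)
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  n <- length(bx)
  negll <- function(par) {
    theta <- par[1]; xi <- par[-1]
    sum((bx - xi)^2 / (2 * sx^2) + (by - theta * xi)^2 / (2 * sy^2))
  }
  theta0 <- mr_ivw(instruments)$estimate
  fit <- optim(c(theta0, bx), negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 1000, reltol = 1e-14))
  if (fit$convergence != 0) {
    stop("maximum-likelihood estimation did not converge (code ",
         fit$convergence, ")", call. = FALSE)
  }
  cov1 <- tryCatch(solve(fit$hessian)[1, 1], error = function(e) NA_real_)
  if (!is.finite(cov1) || cov1 <= 0) {
    stop("observed information is singular; SE unavailable", call. = FALSE)
  }
  se <- sqrt(cov1)
  tibble(estimate = fit$par[1], se = se,
         p_value = 2 * pnorm(-abs(fit$par[1] / se)),
         converged = TRUE)
}

#' Prune pleiotropic instruments by heterogeneity FDR
#'
#' For each variant, computes its Cochran's Q contribution against the
#' leave-one-out IVW estimate (variance bY^2-scale: sY^2 + theta^2 sX^2),
#' converts to a chi-square(1) p-value, applies Benjamini-Hochberg, and
#' removes variants below the FDR cutoff.
#'
#' @inheritParams mr_ivw
#' @param fdr false-discovery-rate cutoff (default 0.2).
#' @return list with `kept` and `removed` instrument tibbles; both carry
#'   `q_contribution` and `q_fdr` columns for audit.
#' @export
pleiotropy_filter <- function(instruments, fdr = 0.2) {
  instruments <- check_instruments(instruments, 4L)
  n <- nrow(instruments)
  q <- p <- double(n)
  for (j in seq_len(n)) {
    theta_j <- mr_ivw(instruments[-j, ])$estimate
    num <- (instruments$beta_outcome[j] -
              theta_j * instruments$beta_exposure[j])^2
    den <- instruments$se_outcome[j]^2 +
      theta_j^2 * instruments$se_exposure[j]^2
    q[j] <- num / den
    p[j] <- pchisq(q[j], df = 1, lower.tail = FALSE)
  }
  padj <- stats::p.adjust(p, method = "BH")
  out <- instruments
  out$q_contribution <- q
  out$q_fdr <- padj
  flagged <- padj < fdr
  list(kept = out[!flagged, ], removed = out[flagged, ])
}

#' Run the full MR estimator suite
#'
#' IVW, MR-Egger, simple and weighted median, and maximum likelihood on
#' one instrument set, optionally after pleiotropy pruning; estimates are
#' reported on the input scale and, when `exponentiate = TRUE`, as odds
#' ratios with 95% CIs (log-odds outcome scale assumed).
#'
#' @inheritParams mr_ivw
#' @param prune apply [pleiotropy_filter()] first.
#' @param fdr FDR cutoff for pruning.
#' @param exponentiate also report exp(estimate) and exp CI bounds.
#' @param n_boot bootstrap draws for median SEs.
#' @return list with `table` (per-method estimates), `egger_intercept`,
#'   and `removed_variants`.
#' @export
mr_suite <- function(instruments, prune = TRUE, fdr = 0.2,
                     exponentiate = TRUE, n_boot = 10000L) {
  removed <- instruments[0, ]
  if (prune && nrow(instruments) >= 4L) {
    pf <- pleiotropy_filter(instruments, fdr)
    instruments <- pf$kept
    removed <- pf$removed
  }
  ivw <- mr_ivw(instruments)
  egger <- mr_egger(instruments)
  med_s <- mr_median(instruments, weighted = FALSE, n_boot = n_boot)
  med_w <- mr_median(instruments, weighted = TRUE, n_boot = n_boot)
  ml <- mr_maxlik(instruments)
  tab <- tibble(
    method = c("ivw", "egger", "simple_median", "weighted_median",
               "maximum_likelihood"),
    estimate = c(ivw$estimate, egger$slope, med_s$estimate, med_w$estimate,
                 ml$estimate),
    se = c(ivw$se, egger$se_slope, med_s$se, med_w$se, ml$se),
    p_value = c(ivw$p_value, egger$p_slope, med_s$p_value, med_w$p_value,
                ml$p_value)
  )
  tab$ci_lower <- tab$estimate - qnorm(0.975) * tab$se
  tab$ci_upper <- tab$estimate + qnorm(0.975) * tab$se
  if (exponentiate) {
    tab$or <- exp(tab$estimate)
    tab$or_lower <- exp(tab$ci_lower)
    tab$or_upper <- exp(tab$ci_upper)
  }
  list(table = tab,
       egger_intercept = egger[, c("intercept", "se_intercept",
                                   "p_intercept")],
       removed_variants = removed)
}

#' Observed-scale to liability-scale heritability
#'
#' Lee transformation: h2_liab = h2_obs * K^2 (1-K)^2 /
#' (z^2 P (1-P)), with K the population prevalence, P the sample
#' prevalence and z the standard normal density at the liability
#' threshold Phi^-1(1 - K).
#'
#' @param h2_observed observed-scale heritability (>= 0).
#' @param sample_prevalence P in (0, 1).
#' @param population_prevalence K in (0, 1).
#' @return liability-scale heritability.
#' @export
liability_h2 <- function(h2_observed, sample_prevalence,
                         population_prevalence) {
  if (h2_observed < 0) stop("`h2_observed` must be >= 0", call. = FALSE)
  check_prob(sample_prevalence, "sample_prevalence",
             open_lower = TRUE, open_upper = TRUE)
  check_prob(population_prevalence, "population_prevalence",
             open_lower = TRUE, open_upper = TRUE)
  K <- population_prevalence
  P <- sample_prevalence
  z <- dnorm(qnorm(1 - K))
  h2_observed * K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
}
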