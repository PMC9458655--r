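#' Exact two-sided binomial p-value
#'
#' Default convention is tail doubling: p = min(1, 2 * min(P[X <= k],
#' P[X >= k])), which is exact and symmetric at p0 = 0.5. The
#' minimum-likelihood convention (sum of outcome probabilities no larger
#' than P[X = k], as in [stats::binom.test()]) is available via `method`.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @param method `"double"` (default) or `"minlike"`.
#' @return p-value in (0, 1].
#' @export
binom_two_sided <- function(k, n, p0 = 0.5, method = c("double", "minlike")) {
  method <- match.arg(method)
  k <- check_count(k, "k", min = 0L)
  n <- check_count(n, "n", min = 1L)
  if (k > n) stop("`k` cannot exceed `n`", call. = FALSE)
  check_prob(p0, "p0", open_lower = TRUE, open_upper = TRUE)
  if (method == "double") {
    lower <- pbinom(k, n, p0)
    upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  } else {
    d <- dbinom(0:n, n, p0)
    sum(d[d <= dbinom(k, n, p0) * (1 + 1e-7)])
  }
}

#' Exact one-sided (upper tail) binomial p-value
#'
#' P[X >= k] under Binomial(n, p0).
#' @inheritParams binom_two_sided
#' @return p-value in (0, 1].
#' @export
binom_one_sided_ge <- function(k, n, p0) {
  k <- check_count(k, "k", min = 0L)
  n <- check_count(n, "n", min = 1L)
  if (k > n) stop("`k` cannot exceed `n`", call. = FALSE)
  check_prob(p0, "p0", open_lower = TRUE, open_upper = TRUE)
  if (k == 0L) return(1)
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Allelic-shift test for one mCA state
#'
#' Among informative heterozygous carriers of the risk haplotype, tests
#' whether events of a given state favor the risk haplotype more often
#' than the 50:50 null. Counting rule: a gain favors the risk haplotype
#' when it is duplicated, a loss when it is retained, a CNLOH when it is
#' duplicated.
#'
#' @param k_risk events favoring the risk haplotype.
#' @param n_informative informative heterozygous carriers with the state.
#' @param state optional label carried into the output.
#' @return tibble (state, k, n, p_value); `p_value` is `NA` (flagged)
#'   when `n_informative` is 0.
#' @export
allelic_shift_test <- function(k_risk, n_informative, state = NA_character_) {
  if (n_informative == 0L) {
    return(tibble(state = state, k = 0L, n = 0L, p_value = NA_real_,
                  note = "no informative carriers"))
  }
  tibble(state = state, k = as.integer(k_risk),
         n = as.integer(n_informative),
         p_value = binom_two_sided(k_risk, n_informative, 0.5),
         note = NA_character_)
}

#' Odds ratio from two proportions
#'
#' OR = odds(p1) / odds(p2).
#' @param p1,p2 proportions strictly inside (0, 1).
#' @return odds ratio.
#' @export
odds_ratio_from_props <- function(p1, p2) {
  check_prob(p1, "p1", open_lower = TRUE, open_upper = TRUE)
  check_prob(p2, "p2", open_lower = TRUE, open_upper = TRUE)
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' Association test on a 2x2 co-occurrence table
#'
#' Odds ratio is the cross-product ratio with a Haldane-Anscombe 0.5
#' correction when any cell is zero. The p-value uses Fisher's exact
#' test for tables up to `exact_max_n` total observations and the
#' chi-square test otherwise; the method used is recorded.
#'
#' @param table2x2 2x2 matrix of nonnegative counts.
#' @param exact_max_n total count above which chi-square is used.
#' @return tibble (odds_ratio, p_value, method).
#' @export
cooccurrence_test <- function(table2x2, exact_max_n = 5000L) {
  m <- as.matrix(table2x2)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0)) {
    stop("`table2x2` must be a 2x2 matrix of nonnegative counts",
         call. = FALSE)
  }
  if (sum(m) == 0) stop("empty table", call. = FALSE)
  mc <- m
  if (any(m == 0)) mc <- m + 0.5
  or <- (mc[1, 1] * mc[2, 2]) / (mc[1, 2] * mc[2, 1])
  if (sum(m) <= exact_max_n) {
    p <- fisher.test(m)$p.value
    method <- "fisher_exact"
  } else {
    p <- suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    method <- "chi_square"
  }
  tibble(odds_ratio = or, p_value = p, method = method)
}

#' Clonal-ordering sign test on paired AF and cellular fractions
#'
#' For samples carrying both a V617F mutation and an mCA over the locus,
#' counts how often the mutation allelic fraction exceeds the mCA
#' cellular fraction. Under the null that neither event systematically
#' precedes the other, the count is Binomial(n, 0.5); ties are dropped
#' by default (classical sign test) or split evenly.
#'
#' @param v617f_af,mca_cf paired numeric vectors in (0, 1].
#' @param tie_policy `"drop"` (default) or `"split"`.
#' @return tibble (k_af_gt_cf, n, p_value); p_value `NA` (flagged) when
#'   no non-tied pairs remain.
#' @export
clonal_order_test <- function(v617f_af, mca_cf,
                              tie_policy = c("drop", "split")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(length(v617f_af) == length(mca_cf))
  ok <- !is.na(v617f_af) & !is.na(mca_cf)
  af <- v617f_af[ok]; cf <- mca_cf[ok]
  gt <- af > cf
  ties <- af == cf
  if (tie_policy == "drop") {
    k <- sum(gt & !ties)
    n <- sum(!ties)
  } else {
    k <- sum(gt) + floor(sum(ties) / 2)
    n <- length(af)
  }
  if (n == 0L) {
    return(tibble(k_af_gt_cf = 0L, n = 0L, p_value = NA_real_,
                  note = "all pairs tied"))
  }
  tibble(k_af_gt_cf = as.integer(k), n = as.integer(n),
         p_value = binom_two_sided(k, n, 0.5), note = NA_character_)
}

#' Enrichment of events at a locus against a reference rate
#'
#' One-sided exact binomial test of the observed carrier count against
#' an external reference rate (e.g. the ~3% mCA rate in population-based
#' surveys of cancer-free individuals).
#'
#' @param observed_k carriers observed.
#' @param n cohort size.
#' @param reference_rate expected carrier probability under the
#'   reference population.
#' @return p-value P[X >= observed_k].
#' @export
locus_enrichment <- function(observed_k, n, reference_rate) {
  check_prob(reference_rate, "reference_rate",
             open_lower = TRUE, open_upper = TRUE)
  binom_one_sided_ge(observed_k, n, reference_rate)
}
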