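#' One-way random-effects intraclass correlation
#'
#' ICC(1): between-group variance share estimated from a one-way ANOVA
#' of technical replicates nested in samples, with an F-based 95%
#' confidence interval.
#'
#' @param values numeric measurements.
#' @param groups grouping factor (one level per sample).
#' @return tibble (icc, ci_lower, ci_upper, ms_between, ms_within); all
#'   `NA` when fewer than two groups are present.
#' @export
icc_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) {
    return(tibble(icc = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                  ms_between = NA_real_, ms_within = NA_real_))
  }
  k <- mean(table(groups))
  fit <- stats::aov(values ~ groups)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- msb / msw
  fl <- f / qf(0.975, df1, df2)
  fu <- f * qf(0.975, df2, df1)
  tibble(icc = icc,
         ci_lower = (fl - 1) / (fl + k - 1),
         ci_upper = (fu - 1) / (fu + k - 1),
         ms_between = msb, ms_within = msw)
}

#' Relative telomere length from qPCR triplicates
#'
#' Per-reaction quantities are interpolated on the (monotone) reference
#' curve from Cq; T and S are the triplicate means; the T/S ratio is
#' passed through the configured transform (`"exp"` by default, the
#' normality-restoring exponentiation; the choice is recorded in the
#' output). Triplicate coefficients of variation above `cv_limit`
#' percent flag the sample. QC metrics: the control sample's CV across
#' replicate records and the one-way random-effects ICC over
#' per-reaction T/S ratios.
#'
#' @param records tibble with sample_id, plate_id, telomere_cq1..3,
#'   reference_cq1..3.
#' @param reference_curve tibble (cq, log10_quantity), monotone in cq.
#' @param transform `"exp"`, `"identity"` or `"log"`.
#' @param cv_limit per-sample triplicate CV flag threshold (percent).
#' @param control_id optional sample_id of the inter-plate control used
#'   for the reported CV; defaults to mean triplicate CV.
#' @return list: `samples` (per-record tibble with t_quantity,
#'   s_quantity, ts_ratio, rtl, cv_t, cv_s, flagged), `qc` (cv, icc and
#'   its CI, transform used).
#' @export
qpcr_rtl <- function(records, reference_curve,
                     transform = c("exp", "identity", "log"),
                     cv_limit = 15, control_id = NULL) {
  transform <- match.arg(transform)
  need <- c("sample_id", paste0("telomere_cq", 1:3),
            paste0("reference_cq", 1:3))
  stopifnot(all(need %in% names(records)))
  cq <- reference_curve$cq
  lq <- reference_curve$log10_quantity
  if (is.unsorted(cq) && is.unsorted(rev(cq))) {
    stop("reference curve must be monotone in cq", call. = FALSE)
  }
  ord <- order(cq)
  cq <- cq[ord]
  lq <- lq[ord]
  interp <- function(x) {
    10^approx(cq, lq, xout = x, rule = 2, ties = "ordered")$y
  }
  tq <- cbind(interp(records$telomere_cq1), interp(records$telomere_cq2),
              interp(records$telomere_cq3))
  sq <- cbind(interp(records$reference_cq1), interp(records$reference_cq2),
              interp(records$reference_cq3))
  t_mean <- rowMeans(tq)
  s_mean <- rowMeans(sq)
  cv <- function(m) 100 * apply(m, 1, sd) / rowMeans(m)
  cv_t <- cv(tq); cv_s <- cv(sq)
  ts <- t_mean / s_mean
  rtl <- switch(transform, exp = exp(ts), identity = ts, log = log(ts))
  samples <- tibble(
    sample_id = records$sample_id,
    plate_id = if ("plate_id" %in% names(records)) records$plate_id
               else NA_character_,
    t_quantity = t_mean, s_quantity = s_mean,
    ts_ratio = ts, rtl = rtl,
    cv_t = cv_t, cv_s = cv_s,
    flagged = cv_t > cv_limit | cv_s > cv_limit
  )
  # per-reaction ratios (replicate i of T paired with replicate i of S)
  ratio_long <- as.numeric(t(tq / sq))
  group_long <- rep(records$sample_id, each = 3L)
  icc <- icc_oneway(ratio_long, group_long)
  cv_report <- if (!is.null(control_id)) {
    ctrl <- samples$ts_ratio[samples$sample_id == control_id]
    100 * sd(ctrl) / mean(ctrl)
  } else {
    mean(c(cv_t, cv_s))
  }
  list(samples = samples,
       qc = list(cv = cv_report, icc = icc$icc,
                 icc_ci = c(icc$ci_lower, icc$ci_upper),
                 transform = transform))
}
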