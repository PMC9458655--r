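#' Simulation configuration for a synthetic myelofibrosis cohort
#'
#' Bundles every rate, effect size and noise level the cohort generator
#' uses. Defaults emulate the joint structure of a myelofibrosis case
#' series: a *JAK2* 46/1 germline risk haplotype carried by ~68.6% of
#' cases, a V617F somatic mutation in ~60.8% that is preferentially
#' acquired on the risk haplotype (carrier odds ratio 2.69) and in *cis*,
#' mosaic chromosomal alterations (mCAs) in ~73.3% that preferentially
#' retain or duplicate the risk haplotype, mutation allelic fractions that
#' exceed the mCA cellular fraction in almost all double-positive samples,
#' and relative telomere length declining linearly with clonal fraction.
#'
#' @param n_samples number of simulated individuals.
#' @param seed root RNG seed; each sample derives child streams from it.
#' @param risk_hap_carrier_freq probability of carrying >= 1 copy of the
#'   46/1 haplotype ("GGC" over rs3780367, rs10974944, rs12343867).
#' @param v617f_prevalence marginal probability of a V617F mutation.
#' @param v617f_or_given_46_1 odds ratio of mutation for 46/1 carriers
#'   versus non-carriers; per-group rates are solved from this and the
#'   marginal prevalence.
#' @param cis_prob_given_het_carrier probability, among heterozygous 46/1
#'   carriers with a mutation, that the mutation sits on the risk
#'   haplotype (cis).
#' @param biallelic_prob probability a mutated sample carries independent
#'   mutations on both germline haplotypes.
#' @param mca_prevalence probability of carrying a detectable mCA.
#' @param mca_state_mix probability vector over c(gain, loss, cnloh);
#'   defaults proportional to 28:16:59 informative events.
#' @param mca_risk_retention_prob per-state probability that the event
#'   favors the risk haplotype in an informative heterozygous carrier;
#'   defaults 23/28 (gain), 14/16 (loss), 51/59 (CNLOH).
#' @param mca_jak2_prob probability, given an mCA, that it spans the
#'   *JAK2* 9p24.1 region (default 378/684).
#' @param cf_distribution cellular-fraction distribution, a list
#'   `list(dist = "beta", shape1, shape2)` on (0, 1].
#' @param af_distribution shape of the V617F allelic-fraction draw,
#'   same format; default shapes are quantile-fitted to a detected-carrier
#'   AF profile with median ~0.70 and interquartile range ~0.38-0.93.
#' @param af_floor lower truncation of the allelic-fraction draw. Carrier
#'   status emulates *detected* mutations, and a mutant haplotype must
#'   clear the 1% read-frequency filter (~2% AF on a balanced
#'   heterozygote), so truth AF is drawn above a small assay floor.
#' @param af_gt_cf_prob probability that AF exceeds the mCA cellular
#'   fraction when both events are present at *JAK2*.
#' @param telomere_baseline_mean,telomere_baseline_sd baseline relative
#'   telomere length (T/S units) before clonal attrition.
#' @param telomere_slope_per_cf rTL change per unit clonal fraction for
#'   non-*JAK2* events (default -0.57).
#' @param telomere_slope_jak2 rTL slope for *JAK2*-spanning mCAs
#'   (default -1.17).
#' @param telomere_floor lower truncation for rTL.
#' @param baf_sd,lrr_sd Gaussian noise SDs for array BAF and LRR signal.
#' @param reads_per_sample default long-read depth per sample.
#' @param read_error_rate per-read error rate in emitted reads (an
#'   erroneous read has one site flipped).
#' @param n_sites_per_chrom array sites per chromosome in the default
#'   site grid.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 933,
                       seed = 1L,
                       risk_hap_carrier_freq = 0.6861,
                       v617f_prevalence = 0.6082,
                       v617f_or_given_46_1 = 2.69,
                       cis_prob_given_het_carrier = 0.80,
                       biallelic_prob = 0.005,
                       mca_prevalence = 0.7331,
                       mca_state_mix = c(gain = 28, loss = 16, cnloh = 59) / 103,
                       mca_risk_retention_prob = c(gain = 23 / 28,
                                                   loss = 14 / 16,
                                                   cnloh = 51 / 59),
                       mca_jak2_prob = 378 / 684,
                       cf_distribution = list(dist = "beta",
                                              shape1 = 2, shape2 = 1.2),
                       af_distribution = list(dist = "beta",
                                              shape1 = 0.884,
                                              shape2 = 0.517),
                       af_floor = 0.03,
                       af_gt_cf_prob = 0.95,
                       telomere_baseline_mean = 2.0,
                       telomere_baseline_sd = 0.30,
                       telomere_slope_per_cf = -0.57,
                       telomere_slope_jak2 = -1.17,
                       telomere_floor = 0.05,
                       baf_sd = 0.03,
                       lrr_sd = 0.14,
                       reads_per_sample = 2000L,
                       read_error_rate = 0.005,
                       n_sites_per_chrom = 1000L) {
  n_samples <- check_count(n_samples, "n_samples")
  check_prob(risk_hap_carrier_freq, "risk_hap_carrier_freq")
  check_prob(v617f_prevalence, "v617f_prevalence")
  check_prob(cis_prob_given_het_carrier, "cis_prob_given_het_carrier")
  check_prob(biallelic_prob, "biallelic_prob")
  check_prob(mca_prevalence, "mca_prevalence")
  check_prob(mca_jak2_prob, "mca_jak2_prob")
  check_prob(af_gt_cf_prob, "af_gt_cf_prob")
  check_prob(af_floor, "af_floor")
  check_prob(read_error_rate, "read_error_rate")
  if (length(mca_state_mix) != 3L || any(mca_state_mix < 0) ||
      abs(sum(mca_state_mix) - 1) > 1e-8) {
    stop("`mca_state_mix` must be 3 nonnegative probabilities summing to 1",
         call. = FALSE)
  }
  if (length(mca_risk_retention_prob) != 3L) {
    stop("`mca_risk_retention_prob` needs one probability per state",
         call. = FALSE)
  }
  for (p in mca_risk_retention_prob) check_prob(p, "mca_risk_retention_prob")
  if (!is.numeric(v617f_or_given_46_1) || v617f_or_given_46_1 <= 0) {
    stop("`v617f_or_given_46_1` must be a positive odds ratio", call. = FALSE)
  }
  names(mca_state_mix) <- names(mca_risk_retention_prob) <-
    c("gain", "loss", "cnloh")
  cfg <- list(
    n_samples = n_samples, seed = as.integer(seed),
    risk_hap_carrier_freq = risk_hap_carrier_freq,
    v617f_prevalence = v617f_prevalence,
    v617f_or_given_46_1 = v617f_or_given_46_1,
    cis_prob_given_het_carrier = cis_prob_given_het_carrier,
    biallelic_prob = biallelic_prob,
    mca_prevalence = mca_prevalence,
    mca_state_mix = mca_state_mix,
    mca_risk_retention_prob = mca_risk_retention_prob,
    mca_jak2_prob = mca_jak2_prob,
    cf_distribution = cf_distribution,
    af_distribution = af_distribution,
    af_floor = af_floor,
    af_gt_cf_prob = af_gt_cf_prob,
    telomere_baseline_mean = telomere_baseline_mean,
    telomere_baseline_sd = telomere_baseline_sd,
    telomere_slope_per_cf = telomere_slope_per_cf,
    telomere_slope_jak2 = telomere_slope_jak2,
    telomere_floor = telomere_floor,
    baf_sd = baf_sd, lrr_sd = lrr_sd,
    reads_per_sample = check_count(reads_per_sample, "reads_per_sample"),
    read_error_rate = read_error_rate,
    n_sites_per_chrom = check_count(n_sites_per_chrom, "n_sites_per_chrom")
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Solve per-group mutation rates from a marginal prevalence and odds ratio
#'
#' Given carrier frequency c, marginal prevalence m and carrier odds ratio
#' OR, finds (p_noncarrier, p_carrier) such that
#' c * p_carrier + (1 - c) * p_noncarrier = m and
#' odds(p_carrier) / odds(p_noncarrier) = OR.
#' @noRd
solve_group_rates <- function(carrier_freq, prevalence, odds_ratio) {
  if (prevalence == 0) return(c(noncarrier = 0, carrier = 0))
  if (prevalence == 1) return(c(noncarrier = 1, carrier = 1))
  p_c_of <- function(p0) {
    o <- odds_ratio * p0 / (1 - p0)
    o / (1 + o)
  }
  f <- function(p0) {
    carrier_freq * p_c_of(p0) + (1 - carrier_freq) * p0 - prevalence
  }
  p0 <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(noncarrier = p0, carrier = p_c_of(p0))
}

draw_dist <- function(n, spec) {
  if (!identical(spec$dist, "beta")) {
    stop("only `beta` distribution specs are supported", call. = FALSE)
  }
  rbeta(n, spec$shape1, spec$shape2)
}

# inverse-CDF draw from a beta spec truncated to [floor, 1]
draw_dist_truncated <- function(n, spec, floor) {
  if (!identical(spec$dist, "beta")) {
    stop("only `beta` distribution specs are supported", call. = FALSE)
  }
  p_lo <- pbeta(floor, spec$shape1, spec$shape2)
  qbeta(p_lo + runif(n) * (1 - p_lo), spec$shape1, spec$shape2)
}

#' Simulate a cohort of individuals with germline and somatic truth
#'
#' Draws, per individual: two germline three-SNP haplotypes at the *JAK2*
#' 46/1 locus; V617F mutation status, background haplotype and allelic
#' fraction; at most one mCA (state, coordinates, cellular fraction,
#' retained haplotype); relative telomere length; and covariates. The
#' returned tibble is the ground truth every downstream caller is scored
#' against.
#'
#' @param config a [sim_config()] object.
#' @return a tibble with one row per sample. `v617f_status` is one of
#'   `none`, `hap1`, `hap2`, `both`; `mca_state` is `NA` or one of
#'   `gain`, `loss`, `cnloh`; `mca_retained_hap` gives the favored
#'   haplotype side.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created by sim_config()", call. = FALSE)
  }
  n <- config$n_samples
  set.seed(config$seed)

  # germline haplotypes: carrier freq 1 - (1 - q)^2 fixes allele freq q
  q <- 1 - sqrt(1 - config$risk_hap_carrier_freq)
  hap1_risk <- runif(n) < q
  hap2_risk <- runif(n) < q
  hap1 <- ifelse(hap1_risk, RISK_HAP, NONRISK_HAP)
  hap2 <- ifelse(hap2_risk, RISK_HAP, NONRISK_HAP)
  carrier <- hap1_risk | hap2_risk
  het_carrier <- xor(hap1_risk, hap2_risk)

  # V617F status: per-group rates solved from marginal prevalence + OR
  rates <- solve_group_rates(config$risk_hap_carrier_freq,
                             config$v617f_prevalence,
                             config$v617f_or_given_46_1)
  p_mut <- ifelse(carrier, rates["carrier"], rates["noncarrier"])
  mutated <- runif(n) < p_mut
  biallelic <- mutated & (runif(n) < config$biallelic_prob)
  # placement: cis-prob applies to informative heterozygous carriers;
  # homozygous backgrounds get a fair coin, non-carriers have only
  # non-risk haplotypes to mutate
  u_place <- runif(n)
  on_risk <- ifelse(het_carrier,
                    u_place < config$cis_prob_given_het_carrier,
                    NA)
  coin <- runif(n) < 0.5
  v617f_status <- rep("none", n)
  v617f_status[mutated & biallelic] <- "both"
  single <- mutated & !biallelic
  pick_hap1 <- ifelse(
    het_carrier,
    ifelse(is.na(on_risk) | !het_carrier, coin,
           (on_risk & hap1_risk) | (!on_risk & !hap1_risk)),
    coin
  )
  v617f_status[single & pick_hap1] <- "hap1"
  v617f_status[single & !pick_hap1] <- "hap2"

  # mCA: single event per sample
  has_mca <- runif(n) < config$mca_prevalence
  state_idx <- sample.int(3L, n, replace = TRUE, prob = config$mca_state_mix)
  states <- c("gain", "loss", "cnloh")[state_idx]
  spans_jak2 <- has_mca & (runif(n) < config$mca_jak2_prob)
  cf <- pmin(pmax(draw_dist(n, config$cf_distribution), 1e-3), 1)

  # retained/duplicated haplotype: risk-haplotype bias only where the
  # sample is an informative heterozygous carrier and the event spans JAK2
  retention_p <- config$mca_risk_retention_prob[states]
  favor_risk <- runif(n) < retention_p
  retained <- ifelse(
    spans_jak2 & het_carrier,
    ifelse((favor_risk & hap1_risk) | (!favor_risk & !hap1_risk),
           "hap1", "hap2"),
    ifelse(runif(n) < 0.5, "hap1", "hap2")
  )

  # coordinates: JAK2 9p24.1 events run from near 9p-ter across the locus;
  # other events are interstitial on chr20
  start_jak2 <- round(runif(n, 5e5, 2.5e6))
  end_jak2 <- round(runif(n, 2.8e7, 4.5e7))
  start_other <- round(runif(n, 2.0e7, 3.0e7))
  end_other <- round(runif(n, 5.0e7, 6.2e7))
  mca_chrom <- ifelse(spans_jak2, "chr9", "chr20")
  mca_start <- ifelse(spans_jak2, start_jak2, start_other)
  mca_end <- ifelse(spans_jak2, end_jak2, end_other)

  # V617F allelic fraction; conditioned on the JAK2 mCA cellular fraction
  # so that AF > CF with probability af_gt_cf_prob in double positives.
  # The draw is truncated below at the assay floor: carrier status
  # emulates detected mutations, whose AF cleared the frequency filter.
  af_base <- draw_dist_truncated(n, config$af_distribution, config$af_floor)
  af_above <- runif(n) < config$af_gt_cf_prob
  af <- ifelse(has_mca & spans_jak2,
               ifelse(af_above, cf + (1 - cf) * af_base, cf * af_base),
               af_base)
  af <- pmin(pmax(af, config$af_floor), 1)

  # telomere length: baseline minus clonal attrition, steeper for JAK2 events
  slope <- ifelse(spans_jak2, config$telomere_slope_jak2,
                  config$telomere_slope_per_cf)
  rtl <- rnorm(n, config$telomere_baseline_mean, config$telomere_baseline_sd) +
    ifelse(has_mca, slope * cf, 0)
  rtl <- pmax(rtl, config$telomere_floor)

  age <- pmin(pmax(round(rnorm(n, 58, 10)), 18), 85)
  sex <- ifelse(runif(n) < 0.55, "male", "female")
  dna_source <- ifelse(runif(n) < 0.85, "whole_blood", "pbmc")

  tibble(
    sample_id = sprintf("S%05d", seq_len(n)),
    hap1 = hap1, hap2 = hap2,
    is_46_1_hap1 = hap1_risk, is_46_1_hap2 = hap2_risk,
    carrier_46_1 = carrier, het_carrier_46_1 = het_carrier,
    v617f_status = v617f_status,
    v617f_af = ifelse(v617f_status == "none", NA_real_, af),
    mca_state = ifelse(has_mca, states, NA_character_),
    mca_chrom = ifelse(has_mca, mca_chrom, NA_character_),
    mca_start = ifelse(has_mca, mca_start, NA_real_),
    mca_end = ifelse(has_mca, mca_end, NA_real_),
    mca_cf = ifelse(has_mca, cf, NA_real_),
    mca_retained_hap = ifelse(has_mca, retained, NA_character_),
    mca_spans_jak2 = ifelse(has_mca, spans_jak2, FALSE),
    rtl = rtl, age = age, sex = sex, dna_source = dna_source,
    child_seed = child_seed(config$seed, seq_len(n))
  )
}

#' Default array site grid for one or more chromosomes
#'
#' Evenly spaced positions over each chromosome (GRCh38 lengths).
#' @param chroms chromosome names, e.g. `"chr9"`.
#' @param n_sites sites per chromosome.
#' @return tibble (chrom, pos), positions strictly increasing per chrom.
#' @export
default_site_grid <- function(chroms = "chr9", n_sites = 1000L) {
  n_sites <- check_count(n_sites, "n_sites")
  out <- lapply(chroms, function(ch) {
    len <- GRCH38_CHROM_LENGTHS[[ch]]
    if (is.null(len)) stop("unknown chromosome: ", ch, call. = FALSE)
    tibble(chrom = ch,
           pos = as.integer(round(seq(1e5, len - 1e5, length.out = n_sites))))
  })
  bind_rows(out)
}

#' Emit phased SNP-array signal for one simulated sample
#'
#' Produces per-site BAF/LRR with phased genotypes using allele-copy
#' accounting. Inside an mCA of cellular fraction f the expected haplotype
#' copy numbers are: CNLOH (1+f, 1-f); loss (1, 1-f); gain (1+f, 1) (the
#' favored haplotype listed first), so expected BAF at a site is the
#' B-allele copy share and expected LRR is log2(total copies / 2).
#'
#' @param sample one row of a [simulate_cohort()] tibble.
#' @param site_grid tibble (chrom, pos), sorted within chromosome.
#' @param baf_sd,lrr_sd Gaussian noise SDs; 0 gives the closed-form means.
#' @param seed RNG seed; defaults to the sample's child stream.
#' @return tibble (sample_id, chrom, pos, baf, lrr, gt) with gt phased as
#'   `"A|B"` (hap1 allele left of the bar).
#' @export
emit_array_signal <- function(sample, site_grid,
                              baf_sd = 0.03, lrr_sd = 0.14,
                              seed = NULL) {
  if (nrow(site_grid) == 0L) stop("empty site grid", call. = FALSE)
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1L)
    sample <- as.list(sample)
  }
  bad <- unlist(tapply(site_grid$pos, site_grid$chrom,
                       function(p) any(diff(p) <= 0)))
  if (any(bad)) stop("site positions must be strictly increasing per chromosome",
                     call. = FALSE)
  if (is.null(seed)) seed <- child_seed(sample$child_seed, 0L, offset = 1L)
  set.seed(seed)
  n <- nrow(site_grid)

  # phased genotype: B-allele indicator per haplotype (population B freq 0.5)
  b1 <- runif(n) < 0.5
  b2 <- runif(n) < 0.5
  gt <- paste0(ifelse(b1, "B", "A"), "|", ifelse(b2, "B", "A"))

  # haplotype copy numbers per site
  c1 <- rep(1, n)
  c2 <- rep(1, n)
  if (!is.na(sample$mca_state)) {
    f <- sample$mca_cf
    in_event <- site_grid$chrom == sample$mca_chrom &
      site_grid$pos >= sample$mca_start & site_grid$pos <= sample$mca_end
    fav <- switch(sample$mca_state,
                  cnloh = c(1 + f, 1 - f),
                  loss = c(1, 1 - f),
                  gain = c(1 + f, 1))
    if (identical(sample$mca_retained_hap, "hap1")) {
      c1[in_event] <- fav[1]; c2[in_event] <- fav[2]
    } else {
      c1[in_event] <- fav[2]; c2[in_event] <- fav[1]
    }
  }
  tot <- c1 + c2
  baf_mean <- (c1 * b1 + c2 * b2) / tot
  lrr_mean <- log2(tot / 2)
  baf <- baf_mean + if (baf_sd > 0) rnorm(n, 0, baf_sd) else 0
  lrr <- lrr_mean + if (lrr_sd > 0) rnorm(n, 0, lrr_sd) else 0
  tibble(
    sample_id = sample$sample_id,
    chrom = site_grid$chrom, pos = site_grid$pos,
    baf = pmin(pmax(baf, 0), 1), lrr = lrr, gt = gt
  )
}

#' Emit long-read allele observations over the JAK2 amplicon
#'
#' Each read reports the three 46/1-tagging SNP alleles plus the V617F
#' site. Reads are drawn from the two germline haplotypes in proportions
#' shifted by any *JAK2*-spanning mCA (favored-haplotype share (1+f)/2 for
#' CNLOH, 1/(2-f) for loss, (1+f)/(2+f) for gain); the mutant allele rides
#' on its background haplotype at frequency `v617f_af`. Errors affect
#' whole reads: a read is erroneous with probability `error_rate`, and an
#' erroneous read has one of its four sites (chosen uniformly) flipped to
#' the alternative allele, emulating residual consensus-read miscalls
#' whose derivative haplotypes stay well below the 1% frequency filter.
#'
#' @param sample one row of a [simulate_cohort()] tibble.
#' @param n_reads read depth (>= 1).
#' @param error_rate per-read error probability.
#' @param seed RNG seed; defaults to the sample's child stream.
#' @return tibble (sample_id, read_id, a1, a2, a3, v617f).
#' @export
emit_reads <- function(sample, n_reads = 2000L, error_rate = 0.005,
                       seed = NULL) {
  n_reads <- check_count(n_reads, "n_reads")
  check_prob(error_rate, "error_rate")
  if (is.data.frame(sample)) {
    stopifnot(nrow(sample) == 1L)
    sample <- as.list(sample)
  }
  if (is.null(seed)) seed <- child_seed(sample$child_seed, 0L, offset = 2L)
  set.seed(seed)

  share1 <- 0.5
  if (!is.na(sample$mca_state) && isTRUE(sample$mca_spans_jak2)) {
    f <- sample$mca_cf
    share_fav <- switch(sample$mca_state,
                        cnloh = (1 + f) / 2,
                        loss = 1 / (2 - f),
                        gain = (1 + f) / (2 + f))
    share1 <- if (identical(sample$mca_retained_hap, "hap1")) share_fav
              else 1 - share_fav
  }
  from_hap1 <- runif(n_reads) < share1
  hap_str <- ifelse(from_hap1, sample$hap1, sample$hap2)

  mut <- rep(FALSE, n_reads)
  st <- sample$v617f_status
  if (st %in% c("hap1", "both")) {
    mut[from_hap1] <- runif(sum(from_hap1)) < sample$v617f_af
  }
  if (st %in% c("hap2", "both")) {
    idx <- !from_hap1
    mut[idx] <- runif(sum(idx)) < sample$v617f_af
  }

  al <- matrix(unlist(strsplit(hap_str, "")), ncol = 3L, byrow = TRUE)
  risk_al <- strsplit(RISK_HAP, "")[[1]]
  nonrisk_al <- strsplit(NONRISK_HAP, "")[[1]]
  if (error_rate > 0) {
    errored <- which(runif(n_reads) < error_rate)
    err_site <- sample.int(4L, length(errored), replace = TRUE)
    for (s in 1:3) {
      idx <- errored[err_site == s]
      al[idx, s] <- ifelse(al[idx, s] == risk_al[s],
                           nonrisk_al[s], risk_al[s])
    }
    idx_m <- errored[err_site == 4L]
    mut[idx_m] <- !mut[idx_m]
  }
  tibble(
    sample_id = sample$sample_id,
    read_id = sprintf("r%06d", seq_len(n_reads)),
    a1 = al[, 1], a2 = al[, 2], a3 = al[, 3],
    v617f = ifelse(mut, "mut", "ref")
  )
}

#' Emit a table of Mendelian-randomization instruments
#'
#' Simulates per-variant exposure/outcome summary statistics under
#' beta_Y = theta * beta_X + alpha_j + noise, with alpha_j nonzero only
#' for variants flagged pleiotropic.
#'
#' @param n_variants number of instruments (>= 3).
#' @param true_effect causal effect theta of exposure on outcome.
#' @param pleiotropy_spec `list(indices = integer(), alpha = numeric())`:
#'   which variants get a direct (pleiotropic) outcome effect and its size.
#' @param seed RNG seed.
#' @param beta_x_range range of true exposure effects (uniform draw).
#' @param se_x exposure standard error (common to all variants).
#' @param se_y_range range of outcome standard errors (uniform draw).
#' @return tibble (variant_id, beta_exposure, se_exposure, beta_outcome,
#'   se_outcome, pleiotropic).
#' @export
emit_instruments <- function(n_variants, true_effect,
                             pleiotropy_spec = list(indices = integer(),
                                                    alpha = 0),
                             seed = 1L,
                             beta_x_range = c(0.05, 0.20),
                             se_x = 0.02,
                             se_y_range = c(0.05, 0.10)) {
  n_variants <- check_count(n_variants, "n_variants", min = 3L)
  set.seed(as.integer(seed))
  bx_true <- runif(n_variants, beta_x_range[1], beta_x_range[2])
  se_y <- runif(n_variants, se_y_range[1], se_y_range[2])
  alpha <- rep(0, n_variants)
  if (length(pleiotropy_spec$indices)) {
    alpha[pleiotropy_spec$indices] <- pleiotropy_spec$alpha
  }
  tibble(
    variant_id = sprintf("rs%05d", seq_len(n_variants)),
    beta_exposure = bx_true + rnorm(n_variants, 0, se_x),
    se_exposure = se_x,
    beta_outcome = true_effect * bx_true + alpha + rnorm(n_variants, 0, se_y),
    se_outcome = se_y,
    pleiotropic = seq_len(n_variants) %in% pleiotropy_spec$indices
  )
}

#' Emit qPCR triplicate records with a known variance structure
#'
#' Generates telomere (T) and single-copy reference (S) reactions in
#' triplicate through a log-linear standard curve. True per-sample T/S
#' ratios are lognormal with log-scale SD `between_sd_log`; each reaction
#' adds independent lognormal noise with log-scale SD `within_sd_log`, so
#' the variance-component structure behind the intraclass correlation is
#' known in closed form.
#'
#' @param n_samples number of samples.
#' @param between_sd_log between-sample SD of log true T/S.
#' @param within_sd_log per-reaction log-scale noise SD.
#' @param mean_log mean of log true T/S.
#' @param seed RNG seed.
#' @param curve standard curve `list(intercept, slope)` mapping
#'   log10(quantity) to Cq via cq = intercept - slope * log10(q).
#' @return `list(records = tibble, curve = tibble(cq, log10_quantity),
#'   truth = tibble)`.
#' @export
emit_qpcr <- function(n_samples, between_sd_log = 0.4, within_sd_log = 0.05,
                      mean_log = 0, seed = 1L,
                      curve = list(intercept = 38, slope = 3.32)) {
  n_samples <- check_count(n_samples, "n_samples")
  set.seed(as.integer(seed))
  log_ts <- rnorm(n_samples, mean_log, between_sd_log)
  to_cq <- function(q) curve$intercept - curve$slope * log10(q)
  rec <- lapply(seq_len(n_samples), function(i) {
    qt <- exp(log_ts[i] + rnorm(3, 0, within_sd_log))
    qs <- exp(rnorm(3, 0, within_sd_log))
    tibble(
      sample_id = sprintf("Q%04d", i),
      plate_id = sprintf("P%02d", (i - 1) %/% 96 + 1),
      telomere_cq1 = to_cq(qt[1]), telomere_cq2 = to_cq(qt[2]),
      telomere_cq3 = to_cq(qt[3]),
      reference_cq1 = to_cq(qs[1]), reference_cq2 = to_cq(qs[2]),
      reference_cq3 = to_cq(qs[3])
    )
  })
  lq <- seq(-4, 4, by = 0.5)
  list(
    records = bind_rows(rec),
    curve = tibble(cq = curve$intercept - curve$slope * lq,
                   log10_quantity = lq),
    truth = tibble(sample_id = sprintf("Q%04d", seq_len(n_samples)),
                   true_ts = exp(log_ts))
  )
}
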