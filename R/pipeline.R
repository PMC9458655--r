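#' Run the long-read caller across a simulated cohort
#'
#' Emits reads for every sample from its child RNG stream and applies
#' the haplotype-table / rare-filter / QC / call chain.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config the [sim_config()] used to build the cohort.
#' @return tibble of per-sample calls keyed by sample_id.
#' @export
cohort_longread_calls <- function(cohort, config) {
  calls <- lapply(seq_len(nrow(cohort)), function(i) {
    reads <- emit_reads(cohort[i, ], n_reads = config$reads_per_sample,
                        error_rate = config$read_error_rate)
    out <- call_longread_sample(reads)
    out$sample_id <- cohort$sample_id[i]
    out
  })
  bind_rows(calls)
}

#' Run the mCA caller across a simulated cohort
#'
#' Emits phased array signal for chromosome 9 plus (when different) the
#' sample's event chromosome, and calls mCAs per sample.
#'
#' @param cohort output of [simulate_cohort()].
#' @param config the [sim_config()] used to build the cohort.
#' @param params [mca_params()] for the caller.
#' @return tibble of calls with a sample_id column (zero rows for
#'   samples with no significant segment).
#' @export
cohort_mca_calls <- function(cohort, config, params = mca_params()) {
  grids <- list()
  get_grid <- function(chroms) {
    key <- paste(chroms, collapse = ",")
    if (is.null(grids[[key]])) {
      grids[[key]] <<- default_site_grid(chroms, config$n_sites_per_chrom)
    }
    grids[[key]]
  }
  calls <- lapply(seq_len(nrow(cohort)), function(i) {
    s <- cohort[i, ]
    chroms <- unique(c("chr9", s$mca_chrom[!is.na(s$mca_chrom)]))
    sig <- emit_array_signal(s, get_grid(chroms),
                             baf_sd = config$baf_sd, lrr_sd = config$lrr_sd)
    out <- call_mcas(sig, params)
    if (nrow(out)) out$sample_id <- s$sample_id
    out
  })
  bind_rows(calls)
}

#' Cohort bookkeeping percentages
#'
#' Headline percentages with explicit numerators and denominators:
#' V617F mutation carriers, 46/1 germline carriers, cis placements among
#' mutated samples, and mCA carriers.
#'
#' @param hap_calls per-sample long-read calls (with sample_id).
#' @param mca_calls per-sample mCA calls (with sample_id).
#' @param n_samples cohort size (denominator for prevalence rows).
#' @return tibble (quantity, k, n, percent); `percent` is `NA` when the
#'   denominator is 0.
#' @export
summarize_cohort <- function(hap_calls, mca_calls, n_samples) {
  pct <- function(k, n) if (n == 0) NA_real_ else 100 * k / n
  n_mut <- sum(hap_calls$v617f_present)
  n_carrier <- sum(hap_calls$carrier_46_1)
  # "cis" bookkeeping counts mutations residing on a risk-haplotype
  # background, so homozygous 46/1 carriers contribute as well
  n_cis <- sum(hap_calls$v617f_present &
                 !is.na(hap_calls$v617f_background) &
                 hap_calls$v617f_background == RISK_HAP)
  n_mca <- length(unique(mca_calls$sample_id))
  rows <- tibble(
    quantity = c("v617f_mutation", "carrier_46_1", "cis_among_mutated",
                 "mca_any"),
    k = c(n_mut, n_carrier, n_cis, n_mca),
    n = c(nrow(hap_calls), nrow(hap_calls), n_mut, n_samples)
  )
  rows$percent <- mapply(pct, rows$k, rows$n)
  rows
}

# calls overlapping the V617F position on chr9
jak2_mca_calls <- function(mca_calls) {
  mca_calls[mca_calls$chrom == V617F_CHROM &
              mca_calls$start_pos <= V617F_POS &
              mca_calls$end_pos >= V617F_POS &
              mca_calls$state != "undetermined", ]
}

#' Germline-somatic interaction statistics for a called cohort
#'
#' Assembles, from detected calls joined to germline phase: per-state
#' allelic-shift binomials over informative heterozygous 46/1 carriers
#' with a *JAK2*-spanning event, the mCA-mutation co-occurrence table,
#' the clonal-ordering sign test (mutation allelic fraction vs mCA
#' cellular fraction), and the cohort mCA enrichment against a
#' population reference rate.
#'
#' @param cohort truth tibble (supplies the germline phase of hap1/hap2,
#'   as population phasing would).
#' @param hap_calls,mca_calls cohort-level call tables.
#' @param reference_mca_rate population mCA rate for the enrichment test.
#' @return list of tibbles: `allelic_shift`, `cooccurrence`,
#'   `clonal_order`, `enrichment`.
#' @export
interaction_stats <- function(cohort, hap_calls, mca_calls,
                              reference_mca_rate = 0.03) {
  jak2 <- jak2_mca_calls(mca_calls)
  # one event per sample: keep the strongest-shift call per sample
  if (nrow(jak2)) {
    jak2 <- jak2 %>% group_by(sample_id) %>%
      arrange(dplyr::desc(abs(phased_dbaf))) %>%
      dplyr::slice(1) %>% ungroup()
  }
  truth_cols <- cohort[, c("sample_id", "is_46_1_hap1", "is_46_1_hap2",
                           "het_carrier_46_1")]
  j <- left_join(jak2, truth_cols, by = "sample_id")
  informative <- j[j$het_carrier_46_1, ]
  shift <- lapply(c("gain", "loss", "cnloh"), function(st) {
    sub <- informative[informative$state == st, ]
    favors_risk <- (sub$favored_hap == "hap1" & sub$is_46_1_hap1) |
      (sub$favored_hap == "hap2" & sub$is_46_1_hap2)
    allelic_shift_test(sum(favors_risk), nrow(sub), state = st)
  })
  shift <- bind_rows(shift)

  has_jak2_mca <- cohort$sample_id %in% jak2$sample_id
  mutated <- cohort$sample_id %in%
    hap_calls$sample_id[hap_calls$v617f_present]
  tab <- table(factor(has_jak2_mca, c(TRUE, FALSE)),
               factor(mutated, c(TRUE, FALSE)))
  cooc <- cooccurrence_test(as.matrix(tab))

  # ordering compares AF on a resolved background haplotype with the mCA
  # cellular fraction; homozygous-background samples are excluded because
  # their measured AF pools reads from both haplotypes
  informative_hap <- hap_calls[hap_calls$v617f_present &
                                 grepl(",", hap_calls$germline_haps),
                               c("sample_id", "v617f_af")]
  both <- left_join(jak2[, c("sample_id", "cell_fraction")],
                    informative_hap, by = "sample_id")
  both <- both[!is.na(both$v617f_af), ]
  order_test <- clonal_order_test(both$v617f_af, both$cell_fraction)

  n_mca <- length(unique(mca_calls$sample_id))
  enr <- tibble(
    k = n_mca, n = nrow(cohort), reference_rate = reference_mca_rate,
    p_value = locus_enrichment(n_mca, nrow(cohort), reference_mca_rate)
  )
  list(allelic_shift = shift, cooccurrence = cooc,
       clonal_order = order_test, enrichment = enr)
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> array signal + mCA calling -> long-read calling ->
#' interaction statistics -> MR suite -> telomere association, writing
#' stage TSVs, a `summary.json` and a run manifest into `out_dir`.
#'
#' @param config a [sim_config()] or the path to a YAML file whose keys
#'   are [sim_config()] arguments.
#' @param out_dir output directory (created if missing).
#' @param mr_theta,mr_n_instruments,mr_n_pleiotropic,mr_alpha parameters
#'   of the demonstration instrument set for the MR stage.
#' @return (invisibly) the summary list written to summary.json.
#' @export
run_pipeline <- function(config, out_dir,
                         mr_theta = 0.5, mr_n_instruments = 19L,
                         mr_n_pleiotropic = 5L, mr_alpha = 0.3) {
  if (is.character(config)) {
    args <- yaml::read_yaml(config)
    config <- do.call(sim_config, args)
  }
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config or a YAML path", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- simulate_cohort(config)
  write_tsv_file(cohort, file.path(out_dir, "cohort_truth.tsv"))

  mca_calls <- cohort_mca_calls(cohort, config)
  write_mca_bed(mca_calls, file.path(out_dir, "mca_calls.bed"))

  hap_calls <- cohort_longread_calls(cohort, config)
  write_tsv_file(hap_calls, file.path(out_dir, "hap_calls.tsv"))

  summary_tab <- summarize_cohort(hap_calls, mca_calls, nrow(cohort))
  write_tsv_file(summary_tab, file.path(out_dir, "cohort_summary.tsv"))

  n_mut <- sum(hap_calls$v617f_present)
  if (n_mut > 0) {
    stats <- interaction_stats(cohort, hap_calls, mca_calls)
  } else {
    stats <- list(note = "no mutated samples; cis and ordering not applicable")
  }

  instruments <- emit_instruments(
    mr_n_instruments, mr_theta,
    pleiotropy_spec = list(indices = seq_len(mr_n_pleiotropic),
                           alpha = mr_alpha),
    seed = child_seed(config$seed, 0L, offset = 5L)
  )
  write_tsv_file(instruments, file.path(out_dir, "instruments.tsv"))
  mr <- mr_suite(instruments, prune = TRUE, n_boot = 2000L)

  # telomere attrition: standard linear fit of rTL on detected clonal
  # fraction (overall, and for JAK2-spanning events)
  mca_best <- mca_calls %>% group_by(sample_id) %>%
    arrange(dplyr::desc(abs(phased_dbaf))) %>% dplyr::slice(1) %>% ungroup()
  tel <- left_join(cohort[, c("sample_id", "rtl")],
                   mca_best[, c("sample_id", "cell_fraction", "chrom",
                                "start_pos", "end_pos")],
                   by = "sample_id")
  tel$cf <- ifelse(is.na(tel$cell_fraction), 0, tel$cell_fraction)
  jak2_ids <- unique(jak2_mca_calls(mca_calls)$sample_id)
  has_jak2 <- tel$sample_id %in% jak2_ids
  # separate fits per event class (plus event-free samples as the cf = 0
  # anchor), so each slope estimates its own attrition rate
  fit_all <- lm(rtl ~ cf, data = tel)
  fit_j <- lm(rtl ~ cf, data = tel[has_jak2 | tel$cf == 0, ])
  fit_o <- lm(rtl ~ cf, data = tel[!has_jak2, ])
  telomere <- list(
    slope_per_cf_marginal = unname(coef(fit_all)[2]),
    slope_per_cf_jak2 = unname(coef(fit_j)[2]),
    slope_per_cf_other = unname(coef(fit_o)[2])
  )

  summary <- list(
    n_samples = nrow(cohort),
    cohort_summary = summary_tab,
    interaction = stats,
    mr = list(table = mr$table,
              egger_intercept = mr$egger_intercept,
              n_removed = nrow(mr$removed_variants),
              removed_variants = mr$removed_variants$variant_id),
    telomere = telomere
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  write_manifest(config, out_dir)
  invisible(summary)
}

#' Write a run manifest with config hash and output digests
#' @noRd
write_manifest <- function(config, out_dir) {
  cfg_file <- tempfile(fileext = ".rds")
  on.exit(unlink(cfg_file))
  saveRDS(config, cfg_file, version = 2)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.json"))
  digests <- tools::md5sum(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("clonalshift")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(setNames(unname(digests), basename(files))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
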