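#' Tuning parameters for the mCA caller
#'
#' Thresholds are deterministic stand-ins for the manual review step used
#' with HMM-based callers: LRR cutoffs separate gain/loss from
#' copy-neutral events, a minimum BAF deviation guards the CNLOH call,
#' and a Bonferroni-corrected scan significance controls segment
#' discovery.
#'
#' @param min_het minimum heterozygous sites for a callable segment.
#' @param alpha familywise significance level for segment discovery
#'   (Bonferroni over all candidate intervals per chromosome).
#' @param lrr_gain_min median LRR above which a segment is a gain.
#' @param lrr_loss_max median LRR below which a segment is a loss.
#' @param min_dbaf_cnloh minimum mean |BAF - 0.5| for a CNLOH call when
#'   LRR is between the gain/loss cutoffs.
#' @param telomere_margin distance (bp) from a chromosome end within
#'   which an event counts as telomeric.
#' @param max_events_per_chrom recursion cap for multiple events.
#' @return a list of class `mca_params`.
#' @export
mca_params <- function(min_het = 20L, alpha = 1e-4,
                       lrr_gain_min = 0.04, lrr_loss_max = -0.10,
                       min_dbaf_cnloh = 0.02, telomere_margin = 1e6,
                       max_events_per_chrom = 5L) {
  p <- list(min_het = check_count(min_het, "min_het"),
            alpha = alpha, lrr_gain_min = lrr_gain_min,
            lrr_loss_max = lrr_loss_max, min_dbaf_cnloh = min_dbaf_cnloh,
            telomere_margin = telomere_margin,
            max_events_per_chrom = check_count(max_events_per_chrom,
                                               "max_events_per_chrom"))
  class(p) <- c("mca_params", "list")
  p
}

# orient het BAF toward haplotype 1: positive mean => hap1 over-represented
oriented_dbaf <- function(baf, gt) {
  sign <- ifelse(gt == "B|A", 1, -1)
  (baf - 0.5) * sign
}

#' Exhaustive best-interval scan
#'
#' Finds the contiguous interval maximizing |sum| / sqrt(length) over a
#' numeric vector (the scan statistic of a mean-shift test with known
#' noise SD). Ties are broken toward the longer interval.
#' @noRd
best_interval <- function(x) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  best <- list(score = -Inf, start = NA_integer_, end = NA_integer_,
               sum = NA_real_)
  for (L in seq_len(n)) {
    sums <- cs[(L + 1):(n + 1)] - cs[1:(n + 1 - L)]
    sc <- abs(sums) / sqrt(L)
    i <- which.max(sc)
    # ">=" so that at equal score a longer interval (later L) wins
    if (sc[i] >= best$score) {
      best <- list(score = sc[i], start = i, end = i + L - 1L, sum = sums[i])
    }
  }
  best
}

# recursive mean-shift segmentation of one signal vector.
# `null_sd` scales the scan statistic; `n_tests` is the fixed Bonferroni
# denominator (all intervals of the full chromosome); `one_sided` accepts
# only positive shifts (used for the |BAF - 0.5| pass).
scan_segments <- function(x, null_sd, alpha, n_tests, one_sided = FALSE,
                          offset = 0L, depth = 1L, max_depth = 5L) {
  n <- length(x)
  if (n < 2L || depth > max_depth) return(list())
  b <- best_interval(x)
  if (!is.finite(b$score)) return(list())
  z <- b$score / null_sd
  p_tail <- if (one_sided) {
    if (b$sum <= 0) return(list())
    pnorm(-z)
  } else {
    2 * pnorm(-z)
  }
  p <- min(1, n_tests * p_tail)
  if (p >= alpha) return(list())
  seg <- list(list(start = offset + b$start, end = offset + b$end, p = p))
  left <- if (b$start > 1L) {
    scan_segments(x[1:(b$start - 1L)], null_sd, alpha, n_tests, one_sided,
                  offset = offset, depth = depth + 1L, max_depth = max_depth)
  } else list()
  right <- if (b$end < n) {
    scan_segments(x[(b$end + 1L):n], null_sd, alpha, n_tests, one_sided,
                  offset = offset + b$end, depth = depth + 1L,
                  max_depth = max_depth)
  } else list()
  c(seg, left, right)
}

merge_intervals <- function(ivs) {
  if (!length(ivs)) return(ivs)
  m <- do.call(rbind, lapply(ivs, function(v) c(v$start, v$end)))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- list(m[1, ])
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      last <- out[[length(out)]]
      if (m[i, 1] <= last[2] + 1L) {
        out[[length(out)]] <- c(last[1], max(last[2], m[i, 2]))
      } else {
        out[[length(out) + 1L]] <- m[i, ]
      }
    }
  }
  lapply(out, function(v) list(start = v[1], end = v[2]))
}

#' Segment BAF signal of one sample into candidate mCA intervals
#'
#' Two-tier detection: (1) a phase-oriented mean-shift scan on
#' (BAF - 0.5) oriented by the phased genotype, which is sensitive to
#' subtle haplotype imbalance; (2) an unphased scan on |BAF - 0.5| minus
#' its null mean, which rescues high-cell-fraction events robustly to
#' phasing. Significant intervals from both passes are overlap-merged.
#' Noise SD is estimated from the median absolute successive difference
#' of the oriented signal, which is insensitive to contained events.
#'
#' @param sites tibble (chrom, pos, baf, lrr, gt) for one sample.
#' @param params an [mca_params()] object.
#' @return tibble of segments (chrom, start_pos, end_pos, n_het,
#'   mean_abs_dbaf, phased_dbaf, median_lrr); zero rows if nothing
#'   significant.
#' @export
segment_baf <- function(sites, params = mca_params()) {
  stopifnot(all(c("chrom", "pos", "baf", "lrr", "gt") %in% names(sites)))
  out <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, ]
    s <- s[order(s$pos), ]
    het <- s$gt %in% c("A|B", "B|A")
    if (!any(het)) {
      warning("chromosome ", ch, " has no heterozygous sites; skipped")
      next
    }
    h <- s[het, ]
    if (nrow(h) < params$min_het) next
    o <- oriented_dbaf(h$baf, h$gt)
    sigma <- mad(diff(o)) / sqrt(2)
    if (sigma <= 0) sigma <- max(sd(diff(o)) / sqrt(2), 1e-6)
    n <- length(o)
    n_tests <- n * (n + 1) / 2
    segs_phase <- scan_segments(o, sigma, params$alpha, n_tests,
                                one_sided = FALSE,
                                max_depth = params$max_events_per_chrom)
    a <- abs(h$baf - 0.5) - sigma * sqrt(2 / pi)
    sd_a <- sigma * sqrt(1 - 2 / pi)
    segs_abs <- scan_segments(a, sd_a, params$alpha, n_tests,
                              one_sided = TRUE,
                              max_depth = params$max_events_per_chrom)
    merged <- merge_intervals(c(segs_phase, segs_abs))
    for (iv in merged) {
      idx <- iv$start:iv$end
      if (length(idx) < params$min_het) next
      start_pos <- h$pos[iv$start]
      end_pos <- h$pos[iv$end]
      in_all <- s$pos >= start_pos & s$pos <= end_pos
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start_pos = start_pos, end_pos = end_pos,
        n_het = length(idx),
        mean_abs_dbaf = mean(abs(h$baf[idx] - 0.5)),
        phased_dbaf = mean(oriented_dbaf(h$baf[idx], h$gt[idx])),
        median_lrr = median(s$lrr[in_all])
      )
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start_pos = integer(),
                  end_pos = integer(), n_het = integer(),
                  mean_abs_dbaf = double(), phased_dbaf = double(),
                  median_lrr = double()))
  }
  arrange(bind_rows(out), chrom, start_pos)
}

#' Classify the copy-number state of a segment
#'
#' Gain if median LRR exceeds `lrr_gain_min`, loss if below
#' `lrr_loss_max`, CNLOH if LRR lies between the cutoffs while the mean
#' BAF deviation is elevated, otherwise undetermined.
#'
#' @param segment one segment row (list or one-row data frame) with
#'   `median_lrr` and `mean_abs_dbaf`.
#' @param params an [mca_params()] object.
#' @return one of `"gain"`, `"loss"`, `"cnloh"`, `"undetermined"`.
#' @export
classify_state <- function(segment, params = mca_params()) {
  if (is.data.frame(segment)) segment <- as.list(segment)
  lrr <- segment$median_lrr
  dbaf <- segment$mean_abs_dbaf
  if (lrr > params$lrr_gain_min) return("gain")
  if (lrr < params$lrr_loss_max) return("loss")
  if (dbaf >= params$min_dbaf_cnloh) return("cnloh")
  "undetermined"
}

#' Cellular fraction from BAF deviation by allele-copy accounting
#'
#' With cellular fraction f, expected het BAF is (1 +/- f)/2 for CNLOH,
#' 1/(2-f) or (1-f)/(2-f) for loss, and (1+f)/(2+f) or 1/(2+f) for gain.
#' Inverting the deviation d = |BAF - 0.5| gives f = 2d (CNLOH),
#' f = 4d/(1+2d) (loss) and f = 4d/(1-2d) (gain, capped at 1 since the
#' gain deviation saturates at 1/6 when every cell carries the event).
#'
#' @param dbaf BAF deviation from 0.5, in `[0, 0.5]`.
#' @param state `"gain"`, `"loss"` or `"cnloh"`.
#' @return cellular fraction in `[0, 1]`.
#' @export
estimate_cell_fraction <- function(dbaf, state) {
  if (!state %in% c("gain", "loss", "cnloh")) {
    stop("cell fraction undefined for state `", state, "`", call. = FALSE)
  }
  if (any(dbaf < 0 | dbaf > 0.5)) {
    stop("`dbaf` must be within [0, 0.5]", call. = FALSE)
  }
  f <- switch(state,
    cnloh = 2 * dbaf,
    loss = 4 * dbaf / (1 + 2 * dbaf),
    gain = {
      over <- dbaf > 1 / 6
      if (any(over)) {
        warning("gain deviation above 1/6; cellular fraction capped at 1")
      }
      ifelse(over, 1, 4 * dbaf / (1 - 2 * dbaf))
    }
  )
  pmin(f, 1)
}

#' Classify the chromosomal region of an event
#'
#' Whole-chromosome if the event covers the full analyzed site extent of
#' its chromosome; telomeric if it lies entirely within
#' `telomere_margin` of either chromosome end; interstitial otherwise.
#'
#' @param start_pos,end_pos event coordinates (1-based inclusive).
#' @param chrom_length chromosome length in bp.
#' @param site_extent optional `c(first, last)` analyzed site positions;
#'   when supplied, covering it entirely classifies as whole-chromosome.
#' @param telomere_margin margin in bp (default 1 Mb).
#' @return `"telomeric"`, `"interstitial"` or `"whole_chromosome"`.
#' @export
classify_region <- function(start_pos, end_pos, chrom_length,
                            site_extent = NULL, telomere_margin = 1e6) {
  stopifnot(chrom_length >= end_pos, end_pos >= start_pos)
  if (!is.null(site_extent) &&
      start_pos <= site_extent[1] && end_pos >= site_extent[2]) {
    return("whole_chromosome")
  }
  if (end_pos <= telomere_margin ||
      start_pos >= chrom_length - telomere_margin) {
    return("telomeric")
  }
  "interstitial"
}

#' Call mosaic chromosomal alterations for one sample
#'
#' Pipeline composition: segment the BAF signal, classify each segment's
#' state from LRR and BAF deviation, convert the phase-oriented BAF shift
#' into a cellular fraction, and classify the chromosomal region. The
#' favored haplotype (`hap1`/`hap2`) is read off the sign of the
#' phase-oriented shift.
#'
#' @param sites tibble (chrom, pos, baf, lrr, gt) for one sample.
#' @param params an [mca_params()] object.
#' @param chrom_lengths named vector of chromosome lengths; defaults to
#'   GRCh38.
#' @return tibble of calls sorted by (chrom, start_pos) with columns
#'   state, cell_fraction, region_class, favored_hap and segment stats.
#' @export
call_mcas <- function(sites, params = mca_params(),
                      chrom_lengths = GRCH38_CHROM_LENGTHS) {
  segs <- segment_baf(sites, params)
  if (!nrow(segs)) {
    return(tibble(chrom = character(), start_pos = integer(),
                  end_pos = integer(), n_het = integer(),
                  mean_abs_dbaf = double(), phased_dbaf = double(),
                  median_lrr = double(), state = character(),
                  cell_fraction = double(), region_class = character(),
                  favored_hap = character()))
  }
  segs$state <- vapply(seq_len(nrow(segs)), function(i) {
    classify_state(segs[i, ], params)
  }, character(1))
  segs$cell_fraction <- vapply(seq_len(nrow(segs)), function(i) {
    if (segs$state[i] == "undetermined") return(NA_real_)
    # the phase-oriented shift is an unbiased deviation estimate; its
    # absolute value feeds the allele-copy inversion
    d <- min(abs(segs$phased_dbaf[i]), 0.5)
    if (segs$state[i] == "gain") d <- min(d, 1 / 6)
    estimate_cell_fraction(d, segs$state[i])
  }, double(1))
  segs$region_class <- vapply(seq_len(nrow(segs)), function(i) {
    ch <- segs$chrom[i]
    pos_ch <- sites$pos[sites$chrom == ch]
    classify_region(segs$start_pos[i], segs$end_pos[i],
                    chrom_length = chrom_lengths[[ch]],
                    site_extent = range(pos_ch),
                    telomere_margin = params$telomere_margin)
  }, character(1))
  segs$favored_hap <- ifelse(segs$phased_dbaf >= 0, "hap1", "hap2")
  arrange(segs, chrom, start_pos)
}

#' Write mCA calls as a BED-like file
#'
#' Converts 1-based inclusive coordinates to BED 0-based half-open.
#' @param calls output of [call_mcas()] (optionally with `sample_id`).
#' @param path output file.
#' @export
write_mca_bed <- function(calls, path) {
  bed <- tibble(
    chrom = calls$chrom,
    start = calls$start_pos - 1L,
    end = calls$end_pos,
    state = calls$state,
    cell_fraction = calls$cell_fraction,
    region_class = calls$region_class,
    n_het = calls$n_het
  )
  if ("sample_id" %in% names(calls)) bed$sample_id <- calls$sample_id
  if ("favored_hap" %in% names(calls)) bed$favored_hap <- calls$favored_hap
  readr::write_tsv(bed, path)
  invisible(path)
}
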