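#' Build a haplotype table from long-read allele observations
#'
#' Collapses reads over the four assayed sites — the three 46/1-tagging
#' SNPs (rs3780367, rs10974944, rs12343867) and the V617F position
#' (GRCh38 chr9:5,073,770) — into distinct 4-site haplotype strings with
#' exact counts and frequencies.
#'
#' @param reads tibble with columns `a1`, `a2`, `a3` (germline alleles)
#'   and `v617f` (`"ref"` or `"mut"`); one row per read.
#' @return tibble (haplotype, background, somatic, count, frequency)
#'   sorted by decreasing count, with attribute `total_reads`.
#' @export
build_haplotype_table <- function(reads) {
  stopifnot(all(c("a1", "a2", "a3", "v617f") %in% names(reads)))
  if (nrow(reads) == 0L) stop("no reads supplied", call. = FALSE)
  background <- paste0(reads$a1, reads$a2, reads$a3)
  hap <- paste0(background, ":", reads$v617f)
  tab <- sort(table(hap), decreasing = TRUE)
  out <- tibble(
    haplotype = names(tab),
    background = sub(":.*$", "", names(tab)),
    somatic = sub("^.*:", "", names(tab)),
    count = as.integer(tab),
    frequency = as.integer(tab) / nrow(reads)
  )
  attr(out, "total_reads") <- nrow(reads)
  out
}

#' Remove rare haplotypes from a haplotype table
#'
#' Drops rows with frequency strictly below `min_freq` (a 1.000%
#' haplotype is retained at the default). Frequencies are computed
#' against the total reads of the sample and are deliberately NOT
#' renormalized after filtering; counts are preserved.
#'
#' @param table output of [build_haplotype_table()].
#' @param min_freq frequency cutoff (default 0.01).
#' @return filtered table, same attributes.
#' @export
filter_rare <- function(table, min_freq = 0.01) {
  keep <- table$frequency >= min_freq
  if (!any(keep)) {
    stop("all haplotypes fall below the frequency cutoff", call. = FALSE)
  }
  out <- table[keep, ]
  attr(out, "total_reads") <- attr(table, "total_reads")
  out
}

#' Sample-level QC of a filtered haplotype table
#'
#' Applies the exclusion rules of the targeted sequencing protocol:
#' samples fail on low depth (total reads below `min_reads`), more than
#' two distinct germline backgrounds after rare-haplotype filtering, or
#' mutations called on more than one germline background. Biallelic
#' mutations are flagged, not silently dropped.
#'
#' @param table filtered haplotype table.
#' @param min_reads depth cutoff (default 1000; a sample at 999 fails).
#' @return one of `"pass"`, `"fail_low_depth"`,
#'   `"fail_many_germline_haps"`, `"fail_biallelic_mutation"`.
#' @export
qc_sample <- function(table, min_reads = 1000L) {
  total <- attr(table, "total_reads")
  if (is.null(total)) total <- sum(table$count)
  if (total < min_reads) return("fail_low_depth")
  backgrounds <- unique(table$background)
  if (length(backgrounds) > 2L) return("fail_many_germline_haps")
  mut_backgrounds <- unique(table$background[table$somatic == "mut"])
  if (length(mut_backgrounds) > 1L) return("fail_biallelic_mutation")
  "pass"
}

#' Call germline haplotypes, V617F status and phase for one sample
#'
#' From a filtered haplotype table: the germline haplotypes are the
#' distinct 3-site backgrounds; 46/1 carriage means any background equals
#' "GGC"; the V617F allelic fraction is mutant reads on the mutated
#' background divided by all reads on that background; phase is cis when
#' the mutated background is the risk haplotype and the sample is
#' heterozygous for it, trans when reversed, and uninformative for
#' homozygous backgrounds.
#'
#' @param table filtered haplotype table.
#' @param qc_status result of [qc_sample()]; calls proceed for `"pass"`
#'   and (flagged) for `"fail_biallelic_mutation"`.
#' @return a one-row tibble (qc_status, germline_haps, carrier_46_1,
#'   het_46_1, v617f_present, v617f_background, v617f_af, phase).
#' @export
call_sample <- function(table, qc_status = qc_sample(table)) {
  backgrounds <- unique(table$background)
  germline <- paste(sort(backgrounds), collapse = ",")
  carrier <- RISK_HAP %in% backgrounds
  het <- length(backgrounds) == 2L && carrier &&
    any(backgrounds != RISK_HAP)
  mut_rows <- table[table$somatic == "mut", ]
  present <- nrow(mut_rows) > 0L
  bg <- af <- NA_character_
  af <- NA_real_
  phase <- NA_character_
  if (present) {
    # biallelic samples report the dominant mutated background, flagged
    bg_counts <- tapply(mut_rows$count, mut_rows$background, sum)
    bg <- names(bg_counts)[which.max(bg_counts)]
    reads_on_bg <- sum(table$count[table$background == bg])
    af <- sum(mut_rows$count[mut_rows$background == bg]) / reads_on_bg
    phase <- if (!het) "uninformative"
             else if (bg == RISK_HAP) "cis"
             else "trans"
  }
  tibble(
    qc_status = qc_status,
    germline_haps = germline,
    carrier_46_1 = carrier,
    het_46_1 = het,
    v617f_present = present,
    v617f_background = if (present) bg else NA_character_,
    v617f_af = af,
    phase = phase
  )
}

#' Full long-read calling for one sample's reads
#'
#' Convenience wrapper: haplotype table, rare-haplotype filter, QC, call.
#' @param reads read table for one sample.
#' @param min_freq rare-haplotype cutoff.
#' @param min_reads QC depth cutoff.
#' @return one-row tibble as [call_sample()], plus `total_reads`.
#' @export
call_longread_sample <- function(reads, min_freq = 0.01, min_reads = 1000L) {
  tab <- filter_rare(build_haplotype_table(reads), min_freq)
  status <- qc_sample(tab, min_reads)
  out <- call_sample(tab, status)
  out$total_reads <- attr(tab, "total_reads")
  out
}

#' Concordance between two calls of the same sample
#'
#' Two sequencing runs agree when the germline haplotype set, the
#' mutation presence and the phase all match.
#' @param call_a,call_b one-row call tibbles.
#' @return TRUE/FALSE.
#' @export
replicate_concordance <- function(call_a, call_b) {
  same_na <- function(x, y) (is.na(x) && is.na(y)) || identical(x, y)
  identical(call_a$germline_haps, call_b$germline_haps) &&
    identical(call_a$v617f_present, call_b$v617f_present) &&
    same_na(call_a$phase, call_b$phase)
}
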