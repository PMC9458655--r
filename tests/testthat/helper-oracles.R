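# independent oracles used across test files

# exhaustive best-scoring interval: double loop over all (i, j),
# score = |sum| / sqrt(length), ties toward the longer interval
brute_force_interval <- function(x) {
  n <- length(x)
  best <- c(score = -Inf, start = NA, end = NA)
  for (i in seq_len(n)) {
    for (j in i:n) {
      sc <- abs(sum(x[i:j])) / sqrt(j - i + 1)
      len <- j - i + 1
      if (sc > best["score"] ||
          (sc == best["score"] && len > best["end"] - best["start"] + 1)) {
        best <- c(score = sc, start = i, end = j)
      }
    }
  }
  best
}

# exact binomial tail / two-sided p by full outcome enumeration
enum_binom_upper <- function(k, n, p0) {
  sum(dbinom(k:n, n, p0))
}
enum_binom_two_sided_double <- function(k, n, p0) {
  lower <- sum(dbinom(0:k, n, p0))
  upper <- sum(dbinom(k:n, n, p0))
  min(1, 2 * min(lower, upper))
}
enum_binom_two_sided_minlike <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= dbinom(k, n, p0) * (1 + 1e-7)])
}

# closed-form expected het BAF values for a state at cellular fraction f
expected_het_bafs <- function(state, f) {
  switch(state,
    cnloh = c((1 - f) / 2, (1 + f) / 2),
    loss = c((1 - f) / (2 - f), 1 / (2 - f)),
    gain = c(1 / (2 + f), (1 + f) / (2 + f))
  )
}
expected_lrr <- function(state, f) {
  switch(state, cnloh = 0, loss = log2((2 - f) / 2), gain = log2((2 + f) / 2))
}

# minimal handmade sample row understood by the emitters
make_sample <- function(hap1 = "GGC", hap2 = "TCT",
                        v617f_status = "none", v617f_af = NA_real_,
                        mca_state = NA_character_, mca_chrom = NA_character_,
                        mca_start = NA_real_, mca_end = NA_real_,
                        mca_cf = NA_real_, mca_retained_hap = NA_character_,
                        mca_spans_jak2 = FALSE, child_seed = 99L) {
  tibble::tibble(
    sample_id = "T00001", hap1 = hap1, hap2 = hap2,
    is_46_1_hap1 = hap1 == "GGC", is_46_1_hap2 = hap2 == "GGC",
    carrier_46_1 = hap1 == "GGC" | hap2 == "GGC",
    het_carrier_46_1 = xor(hap1 == "GGC", hap2 == "GGC"),
    v617f_status = v617f_status, v617f_af = v617f_af,
    mca_state = mca_state, mca_chrom = mca_chrom,
    mca_start = mca_start, mca_end = mca_end, mca_cf = mca_cf,
    mca_retained_hap = mca_retained_hap, mca_spans_jak2 = mca_spans_jak2,
    rtl = 1, age = 60, sex = "male", dna_source = "whole_blood",
    child_seed = child_seed
  )
}

# truth-level expected long-read call for comparing caller output
expected_phase <- function(sample) {
  if (sample$v617f_status == "none") return(NA_character_)
  if (!sample$het_carrier_46_1) return("uninformative")
  mut_hap <- sample$v617f_status
  if (mut_hap == "both") return(NA_character_)
  bg <- if (mut_hap == "hap1") sample$hap1 else sample$hap2
  if (bg == "GGC") "cis" else "trans"
}
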