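#' Validate that a value is a single probability
#' @noRd
check_prob <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single numeric value", name), call. = FALSE)
  }
  lo_ok <- if (open_lower) x > 0 else x >= 0
  hi_ok <- if (open_upper) x < 1 else x <= 1
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is not a valid probability", name, x),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Derive a reproducible child seed from a root seed
#'
#' Each simulated sample owns an RNG stream keyed by (root seed, index);
#' downstream emitters add a fixed per-purpose offset so signal, reads and
#' qPCR draws never share a stream. Kept below 2^31 - 1.
#' @noRd
child_seed <- function(root_seed, index, offset = 0L) {
  as.integer((as.numeric(root_seed) * 48271 + index * 7919 + offset * 104729)
             %% 2147483629)
}

#' Write a table as TSV
#' @noRd
write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

read_tsv_file <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}
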