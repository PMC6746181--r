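DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
NULL

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

random_dna <- function(n, length) {
  if (n == 0L) return(character(0))
  chars <- sample(DNA_BASES, n * length, replace = TRUE)
  m <- matrix(chars, nrow = length)
  do.call(paste0, as.data.frame(t(m), stringsAsFactors = FALSE))
}

#' Substitute random sequencing errors into a vector of sequences
#'
#' Each base of each sequence is independently replaced, with probability
#' `rate`, by one of the three other bases (uniformly). Vectorised: only
#' sequences that actually receive an error are rewritten.
#'
#' @param seqs character vector of DNA sequences.
#' @param rate per-base substitution probability in \[0, 1\].
#' @return character vector of the same length with errors applied.
#' @keywords internal
apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  flat <- sort(sample.int(total, n_err))
  ends <- cumsum(lens)
  read_idx <- findInterval(flat - 1L, ends) + 1L
  pos <- flat - c(0L, ends)[read_idx]
  by_read <- split(pos, read_idx)
  idx <- as.integer(names(by_read))
  fixed <- vapply(seq_along(idx), function(i) {
    s <- strsplit(seqs[idx[i]], "", fixed = TRUE)[[1L]]
    for (p in by_read[[i]]) {
      s[p] <- sample(setdiff(DNA_BASES, s[p]), 1L)
    }
    paste(s, collapse = "")
  }, character(1))
  seqs[idx] <- fixed
  seqs
}

hamming_dist <- function(a, b) {
  # a, b: equal-length strings
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' All sequences at Hamming distance exactly 1 from a DNA string
#' @keywords internal
hamming1_neighbours <- function(umi) {
  chars <- strsplit(umi, "", fixed = TRUE)[[1L]]
  out <- character(0)
  for (i in seq_along(chars)) {
    for (b in setdiff(DNA_BASES, chars[i])) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}
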