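# In-silico tryptic digestion.

#' Digestion parameters
#'
#' @param missed_cleavages allowed internal K/R sites per peptide (0-2).
#' @param min_len,max_len retained peptide length bounds.
#' @return list of class `digest_params`.
#' @export
digest_params <- function(missed_cleavages = 1L, min_len = 5L, max_len = 60L) {
  stopifnot(missed_cleavages >= 0L, missed_cleavages <= 2L,
            min_len >= 1L, max_len >= min_len)
  structure(list(enzyme = "trypsin", missed_cleavages = as.integer(missed_cleavages),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "digest_params")
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to K or R except when the next residue is P, then
#' enumerates peptides spanning up to `missed_cleavages` internal sites and
#' applies the length filter.
#'
#' @param aa_sequence protein sequence (standard residues, `X` allowed and
#'   treated as an ordinary non-site residue).
#' @param params a [digest_params()] object.
#' @return data.frame with columns `peptide`, `start` (1-based on the input),
#'   `missed` (number of internal sites).
#' @export
digest <- function(aa_sequence, params = digest_params()) {
  residues <- aa_check(aa_sequence, allow_x = TRUE, what = "aa_sequence")
  n <- length(residues)
  # cut after position i when residue i is K/R and residue i+1 is not P
  cut_after <- which(residues[-n] %in% c("K", "R") & residues[-1] != "P")
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_frag <- length(starts)
  rows <- list()
  for (i in seq_len(n_frag)) {
    for (m in 0:params$missed_cleavages) {
      j <- i + m
      if (j > n_frag) break
      s <- starts[i]; e <- ends[j]
      len <- e - s + 1L
      if (len < params$min_len || len > params$max_len) next
      rows[[length(rows) + 1L]] <- list(
        peptide = paste(residues[s:e], collapse = ""),
        start = s, missed = m
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), start = integer(),
                      missed = integer(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    peptide = vapply(rows, `[[`, character(1), "peptide"),
    start = vapply(rows, `[[`, integer(1), "start"),
    missed = vapply(rows, `[[`, integer(1), "missed"),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$missed), , drop = FALSE]
}
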