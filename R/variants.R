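# Variant naming and signal-peptide completion within protein families.

#' Assign Greek-letter variant labels within a protein family
#'
#' Variants of a byssal protein family are labelled with Greek letters
#' (alpha, beta, gamma, ...) in strictly decreasing order of mature molecular
#' weight; ties are broken by lexicographic amino-acid sequence, then by
#' transcript id.
#'
#' @param family data.frame of isoforms with columns `mature_mass_kda`,
#'   `aa_sequence` and (optionally) `transcript_id`.
#' @return the same data.frame with a `variant_label` column added, rows in
#'   their original order.
#' @export
assign_variant_names <- function(family) {
  n <- nrow(family)
  if (!n) stop("family is empty", call. = FALSE)
  if (n > length(GREEK_LETTERS)) {
    stop("family has ", n, " variants; the Greek alphabet (",
         length(GREEK_LETTERS), " letters) is exhausted", call. = FALSE)
  }
  tid <- if ("transcript_id" %in% names(family)) family$transcript_id else ""
  ord <- order(-family$mature_mass_kda, family$aa_sequence, tid)
  family$variant_label <- NA_character_
  family$variant_label[ord] <- GREEK_LETTERS[seq_len(n)]
  family
}

#' Complete truncated N-termini using an intact variant of the same component
#'
#' Assembled transcripts are often 5'-truncated, so some variants carry only a
#' partial signal peptide. When another variant of the same component has a
#' complete N-terminus (start codon plus signal annotation) and the truncated
#' variant's sequence overlaps it exactly over at least `min_overlap`
#' residues, the truncated variant is extended with the donor's prefix and
#' inherits the donor's cleavage site (`signal_source = "variant_completion"`).
#'
#' @param family data.frame of isoforms with columns `aa_sequence`,
#'   `has_start`, `signal_pos` (cleavage position or `NA`) and optionally
#'   `signal_source`.
#' @param min_overlap minimum exact overlap in residues (default 10).
#' @return the family with completed sequences; a `completed` logical column
#'   records which rows were extended.
#' @export
complete_signal_from_variants <- function(family, min_overlap = 10L) {
  if (!"signal_source" %in% names(family)) {
    family$signal_source <- ifelse(is.na(family$signal_pos), NA_character_,
                                   "annotation_file")
  }
  family$completed <- FALSE
  donors <- which(family$has_start & !is.na(family$signal_pos))
  if (!length(donors)) return(family)
  acceptors <- which(!(family$has_start & !is.na(family$signal_pos)))
  for (a in acceptors) {
    acc <- family$aa_sequence[a]
    for (d in donors) {
      don <- family$aa_sequence[d]
      sig <- family$signal_pos[d]
      # find the smallest p > 1 such that the acceptor's start reproduces
      # don[p..] exactly over the donor's N-terminal region (signal plus a
      # 10-aa margin into the mature sequence; variants may diverge further
      # downstream)
      done <- FALSE
      for (p in 2:nchar(don)) {
        tail_len <- nchar(don) - p + 1L
        window <- max(min_overlap, sig - p + 1L + 10L)
        ol <- min(tail_len, nchar(acc), window)
        if (ol < min_overlap) break
        if (substr(don, p, p + ol - 1L) == substr(acc, 1L, ol)) {
          family$aa_sequence[a] <- paste0(substr(don, 1L, p - 1L), acc)
          family$has_start[a] <- TRUE
          family$signal_pos[a] <- family$signal_pos[d]
          family$signal_source[a] <- "variant_completion"
          family$completed[a] <- TRUE
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!family$completed[a]) {
      warning("no exact >=", min_overlap, "-aa overlap found to complete ",
              "truncated variant at row ", a, call. = FALSE)
    }
  }
  family
}
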