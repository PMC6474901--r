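# Transcriptome ingestion, six-frame translation, ORF extraction and
# assembly statistics.

#' Read an assembled transcriptome FASTA
#'
#' Reads a nucleotide FASTA and returns one row per transcript. Trinity-style
#' identifiers of the form `comp<N>_c<K>_seq<J>` are parsed so that all
#' transcripts of a component (a gene-like cluster of similar contigs) share a
#' `component_id`; identifiers without the `comp<N>_c<K>` prefix become
#' singleton components under their own id. Sequences are upper-cased and RNA
#' `U` is mapped to `T`.
#'
#' @param fasta_source path to a nucleotide FASTA file.
#' @return data.frame with columns `id`, `component_id`, `sequence`,
#'   `length_bp`.
#' @export
read_transcripts <- function(fasta_source) {
  if (!file.exists(fasta_source)) {
    stop("FASTA file not found: ", fasta_source, call. = FALSE)
  }
  lines <- readLines(fasta_source, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    stop("empty input: no FASTA records in ", fasta_source, call. = FALSE)
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: line ", nonblank[1],
         " does not start a record ('>') in ", fasta_source, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(fasta_source)
  if (!length(set)) {
    stop("empty input: no FASTA records in ", fasta_source, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("malformed FASTA: non-nucleotide characters in record '",
         names(set)[which(bad)[1]], "'", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  data.frame(
    id = ids,
    component_id = parse_component_id(ids),
    sequence = unname(seqs),
    length_bp = unname(nchar(seqs)),
    stringsAsFactors = FALSE
  )
}

#' Parse Trinity-style component identifiers
#'
#' @param ids character vector of transcript ids.
#' @return character vector: the `comp<N>_c<K>` prefix where present,
#'   otherwise the id itself (singleton component).
#' @export
parse_component_id <- function(ids) {
  m <- regmatches(ids, regexpr("^comp[0-9]+_c[0-9]+", ids))
  out <- ids
  has <- grepl("^comp[0-9]+_c[0-9]+", ids)
  out[has] <- m
  out
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1`, `+2`, `+3` translate the forward strand at offsets 0, 1, 2;
#' frames `-1`, `-2`, `-3` translate the reverse complement at the same
#' offsets. The standard genetic code is used, stop codons are rendered `*`,
#' a trailing 1-2 nt partial codon is dropped, and any codon containing `N`
#' translates to `X`.
#'
#' @param sequence nucleotide string over `{A,C,G,T,N}` (a `Transcript` row's
#'   `sequence`), length >= 3.
#' @return named character vector of 6 amino-acid strings, names
#'   `c("+1","+2","+3","-1","-2","-3")`.
#' @export
six_frame_translate <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("sequence must be a single string", call. = FALSE)
  }
  sequence <- chartr("U", "T", toupper(sequence))
  if (nchar(sequence) < 3L) {
    stop("sequence shorter than one codon (length ",
         nchar(sequence), ")", call. = FALSE)
  }
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  translate_offset <- function(dna, off) {
    n <- length(dna) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    sub <- Biostrings::subseq(dna, start = off + 1L, width = n)
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  }
  out <- c(
    vapply(0:2, function(o) translate_offset(fwd, o), character(1)),
    vapply(0:2, function(o) translate_offset(rev, o), character(1))
  )
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Extract open reading frames from a six-frame translation
#'
#' Splits each frame on stop codons (`*`) and keeps segments of at least
#' `min_aa` residues. Under the default `mode = "keep_all"` segments are kept
#' whether or not they begin with Met, because assembled byssal transcripts
#' are frequently 5'-truncated and their proteins can lack observed start
#' codons; `mode = "require_start"` trims each segment to its first Met and
#' drops segments without one.
#'
#' @param frames named character vector as returned by
#'   [six_frame_translate()].
#' @param min_aa minimum ORF length in residues (default 30).
#' @param mode `"keep_all"` or `"require_start"`.
#' @param transcript_id id recorded on each isoform (optional).
#' @return data.frame with columns `transcript_id`, `frame`, `aa_sequence`,
#'   `aa_start` (1-based position in the frame translation), `has_start`,
#'   `has_stop`.
#' @export
extract_orfs <- function(frames, min_aa = 30L, mode = c("keep_all", "require_start"),
                         transcript_id = NA_character_) {
  mode <- match.arg(mode)
  if (min_aa < 1L) stop("min_aa must be >= 1", call. = FALSE)
  rows <- list()
  for (fr in names(frames)) {
    aa <- frames[[fr]]
    if (!nzchar(aa)) next
    # split retaining coordinates
    parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
    pos <- 1L
    n_parts <- length(parts)
    ends_with_stop <- endsWith(aa, "*")
    for (k in seq_len(n_parts)) {
      seg <- parts[k]
      seg_start <- pos
      pos <- pos + nchar(seg) + 1L
      if (!nzchar(seg)) next
      followed_by_stop <- k < n_parts || ends_with_stop
      has_start <- startsWith(seg, "M")
      if (mode == "require_start" && !has_start) {
        m_at <- regexpr("M", seg, fixed = TRUE)
        if (m_at < 0) next
        seg_start <- seg_start + m_at - 1L
        seg <- substring(seg, m_at)
        has_start <- TRUE
      }
      if (nchar(seg) < min_aa) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = transcript_id, frame = fr, aa_sequence = seg,
        aa_start = seg_start, has_start = has_start,
        has_stop = followed_by_stop, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), frame = character(),
                      aa_sequence = character(), aa_start = integer(),
                      has_start = logical(), has_stop = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Translate and extract ORFs for a table of transcripts
#'
#' Convenience wrapper: applies [six_frame_translate()] and [extract_orfs()]
#' to each row of a transcript table and assigns stable isoform ids of the
#' form `<transcript_id>|<frame>|<aa_start>`.
#'
#' @param transcripts data.frame from [read_transcripts()].
#' @inheritParams extract_orfs
#' @return data.frame of isoforms with an `isoform_id` and `component_id`
#'   column added.
#' @export
translate_transcripts <- function(transcripts, min_aa = 30L,
                                  mode = c("keep_all", "require_start")) {
  mode <- match.arg(mode)
  res <- lapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    if (t$length_bp < 3L) return(NULL)
    orfs <- extract_orfs(six_frame_translate(t$sequence), min_aa = min_aa,
                         mode = mode, transcript_id = t$id)
    if (!nrow(orfs)) return(NULL)
    orfs$component_id <- t$component_id
    orfs
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(transcript_id = character(), frame = character(),
                      aa_sequence = character(), aa_start = integer(),
                      has_start = logical(), has_stop = logical(),
                      component_id = character(), isoform_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$isoform_id <- paste(out$transcript_id, out$frame, out$aa_start, sep = "|")
  rownames(out) <- NULL
  out
}

#' Assembly summary statistics
#'
#' Computes the transcript and component counts, the median contig length and
#' the N50/N30 lengths. `Nxx` is the length `L` such that contigs of length
#' `>= L` together contain at least `xx`% of all assembled bases.
#'
#' @param transcripts data.frame from [read_transcripts()] (or any data.frame
#'   with `length_bp` and optionally `component_id`).
#' @return list with `n_transcripts`, `n_components`, `median_bp`, `N50_bp`,
#'   `N30_bp`.
#' @export
assembly_stats <- function(transcripts) {
  if (!nrow(transcripts)) stop("no transcripts supplied", call. = FALSE)
  len <- sort(transcripts$length_bp, decreasing = TRUE)
  total <- sum(as.numeric(len))
  nxx <- function(frac) {
    len[which(cumsum(as.numeric(len)) >= frac * total)[1]]
  }
  list(
    n_transcripts = length(len),
    n_components = if ("component_id" %in% names(transcripts)) {
      length(unique(transcripts$component_id))
    } else NA_integer_,
    median_bp = stats::median(transcripts$length_bp),
    N50_bp = nxx(0.5),
    N30_bp = nxx(0.3)
  )
}
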