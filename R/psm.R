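# Peptide-spectrum-match ingestion, modification handling, peptide-to-isoform
# mapping, spectral counting and protein grouping.

PSM_COLUMNS <- c("sample", "peptide", "peptide_score", "alc",
                 "is_de_novo_only", "protein_score", "transcript_hint")

#' Read a PSM table
#'
#' Expects a TSV with columns `sample`, `peptide`, `peptide_score`, `alc`,
#' `is_de_novo_only` and optionally `protein_score`, `transcript_hint`.
#' Peptides may carry lower-case modification marks (see
#' [expand_modification_keys()]).
#'
#' @param path TSV file path.
#' @return validated data.frame of PSM records.
#' @export
read_psms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "peptide", "peptide_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("PSM table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"alc" %in% names(df)) df$alc <- NA_real_
  if (!"is_de_novo_only" %in% names(df)) df$is_de_novo_only <- FALSE
  if (!"protein_score" %in% names(df)) df$protein_score <- NA_real_
  if (!"transcript_hint" %in% names(df)) df$transcript_hint <- NA_character_
  df$is_de_novo_only <- as.logical(df$is_de_novo_only)
  validate_psms(df)
}

validate_psms <- function(psms) {
  if (any(nchar(gsub("[a-z]", "", psms$peptide)) +
          nchar(gsub("[^a-z]", "", psms$peptide)) < 5L)) {
    stop("PSM peptides must be at least 5 residues long", call. = FALSE)
  }
  if (any(!is.na(psms$peptide_score) & psms$peptide_score < 0)) {
    stop("peptide scores must be >= 0", call. = FALSE)
  }
  psms
}

#' Resolve modification marks on a peptide string
#'
#' Peptides from the upstream search carry lower-case marks: `n`/`q` for
#' deamidated Asn/Gln and `y` for hydroxylated Tyr (DOPA). Marks never change
#' which template residue the position matches -- they only annotate it -- so
#' the match key is the upper-cased backbone.
#'
#' @param peptide peptide string, possibly containing `n`, `q`, `y` marks.
#' @return list with `backbone` (plain upper-case sequence) and `mods`
#'   (data.frame of `pos`, `residue`, `type`).
#' @export
expand_modification_keys <- function(peptide) {
  residues <- strsplit(peptide, "", fixed = TRUE)[[1]]
  lower <- which(residues %in% letters)
  bad <- lower[!residues[lower] %in% c("n", "q", "y")]
  if (length(bad)) {
    stop("modification mark '", residues[bad[1]], "' at position ", bad[1],
         " is not one of n (deamidated N), q (deamidated Q), y (hydroxylated Y)",
         call. = FALSE)
  }
  backbone <- toupper(peptide)
  aa_check(backbone, allow_x = FALSE, what = "peptide backbone")
  type <- c(n = "deamidation", q = "deamidation", y = "hydroxylation")
  mods <- data.frame(
    pos = lower,
    residue = toupper(residues[lower]),
    type = unname(type[residues[lower]]),
    stringsAsFactors = FALSE
  )
  list(backbone = backbone, mods = mods)
}

#' Map PSMs onto protein isoforms
#'
#' Each PSM's backbone is exact-substring matched against every isoform
#' sequence; isoleucine and leucine are treated as indistinguishable by
#' default because MS cannot separate them. A PSM may hit several isoforms
#' (shared-peptide ambiguity is preserved). Per isoform the function
#' aggregates per-sample spectral counts, the unique peptide set, coverage of
#' the mature sequence, and a protein score: the maximum supplied
#' protein-level score, with a documented fallback to the sum of the top
#' three peptide scores when none is supplied.
#'
#' Peptides may match anywhere in the isoform; matches whose termini are not
#' tryptic (preceded by K/R and ending in K/R, or at a protein terminus) are
#' flagged in the per-peptide detail rather than rejected, since gel-band
#' digests commonly show ragged termini.
#'
#' @param psms data.frame of PSM records (see [read_psms()]).
#' @param isoforms data.frame with `isoform_id`, `aa_sequence` and optionally
#'   `signal_pos` (used for mature-sequence coverage) and `transcript_id`.
#' @param il_equivalent treat I and L as equal (default TRUE).
#' @return list with `evidence` (one row per isoform with >= 1 match; columns
#'   `isoform_id`, `protein_score`, `n_unique_peptides`, `coverage_pct`,
#'   spectral count columns `count_<sample>`, `n_psms`, and a `detail`
#'   list-column of per-match data.frames) and `unmatched` (PSM rows hitting
#'   no isoform).
#' @export
map_psms <- function(psms, isoforms, il_equivalent = TRUE) {
  psms <- validate_psms(psms)
  if (!"signal_pos" %in% names(isoforms)) isoforms$signal_pos <- NA_integer_
  if (!"protein_score" %in% names(psms)) psms$protein_score <- NA_real_
  if (!"transcript_hint" %in% names(psms)) psms$transcript_hint <- NA_character_
  if (!"is_de_novo_only" %in% names(psms)) psms$is_de_novo_only <- FALSE
  if (!"alc" %in% names(psms)) psms$alc <- NA_real_

  keyify <- function(x) if (il_equivalent) chartr("I", "L", x) else x
  iso_keys <- keyify(isoforms$aa_sequence)
  backbones <- vapply(psms$peptide, function(p) expand_modification_keys(p)$backbone,
                      character(1), USE.NAMES = FALSE)
  pep_keys <- keyify(backbones)

  samples <- unique(psms$sample)
  n_iso <- nrow(isoforms)
  hits <- vector("list", n_iso)          # per isoform: list of match rows
  matched_any <- logical(nrow(psms))

  for (p in seq_len(nrow(psms))) {
    pk <- pep_keys[p]
    for (i in seq_len(n_iso)) {
      at <- gregexpr(pk, iso_keys[i], fixed = TRUE)[[1]]
      if (at[1] == -1L) next
      matched_any[p] <- TRUE
      hits[[i]][[length(hits[[i]]) + 1L]] <- data.frame(
        psm_row = p, peptide = psms$peptide[p], backbone = backbones[p],
        sample = psms$sample[p], peptide_score = psms$peptide_score[p],
        alc = psms$alc[p], is_de_novo_only = psms$is_de_novo_only[p],
        start = as.integer(at), stringsAsFactors = FALSE
      )
    }
  }

  ev_rows <- list()
  for (i in seq_len(n_iso)) {
    if (is.null(hits[[i]])) next
    det <- do.call(rbind, hits[[i]])
    rownames(det) <- NULL
    det$end <- det$start + nchar(det$backbone) - 1L
    iso_seq <- isoforms$aa_sequence[i]
    iso_res <- strsplit(iso_seq, "", fixed = TRUE)[[1]]
    det$nontryptic <-
      !((det$start == 1L | iso_res[pmax(det$start - 1L, 1L)] %in% c("K", "R")) &
        (det$end == nchar(iso_seq) | iso_res[det$end] %in% c("K", "R")))
    sp <- isoforms$signal_pos[i]
    mat_start <- if (is.na(sp)) 1L else sp + 1L
    mature_len <- nchar(iso_seq) - mat_start + 1L
    covered <- rep(FALSE, mature_len)
    for (r in seq_len(nrow(det))) {
      s <- max(det$start[r], mat_start); e <- det$end[r]
      if (e >= s) covered[(s - mat_start + 1L):(e - mat_start + 1L)] <- TRUE
    }
    # spectral counts: one count per PSM row (not per occurrence within the
    # isoform), so multi-site peptides are not double counted
    psm_rows <- unique(det$psm_row)
    cnt <- table(factor(psms$sample[psm_rows], levels = samples))
    supplied <- psms$protein_score[psm_rows]
    hint <- psms$transcript_hint[psm_rows]
    tid <- if ("transcript_id" %in% names(isoforms)) isoforms$transcript_id[i] else NA
    use <- !is.na(supplied) & (is.na(hint) | hint == tid |
                               hint == isoforms$isoform_id[i])
    protein_score <- if (any(use)) max(supplied[use]) else {
      top <- sort(psms$peptide_score[psm_rows], decreasing = TRUE)
      sum(top[seq_len(min(3L, length(top)))])
    }
    row <- data.frame(
      isoform_id = isoforms$isoform_id[i],
      protein_score = protein_score,
      n_unique_peptides = length(unique(det$backbone)),
      n_psms = length(psm_rows),
      coverage_pct = 100 * sum(covered) / mature_len,
      stringsAsFactors = FALSE
    )
    for (s in samples) row[[paste0("count_", s)]] <- as.integer(cnt[[s]])
    row$detail <- I(list(det))
    ev_rows[[length(ev_rows) + 1L]] <- row
  }
  evidence <- if (length(ev_rows)) {
    out <- do.call(rbind, ev_rows); rownames(out) <- NULL; out
  } else {
    data.frame(isoform_id = character(), protein_score = numeric(),
               n_unique_peptides = integer(), n_psms = integer(),
               coverage_pct = numeric(), stringsAsFactors = FALSE)
  }
  list(evidence = evidence, unmatched = psms[!matched_any, , drop = FALSE])
}

#' Group isoforms by shared peptide evidence
#'
#' Isoforms whose matched peptide sets are identical to, or subsets of,
#' another isoform's set are merged into one group anchored on the isoform
#' with the largest peptide set (ties broken by higher protein score).
#'
#' @param evidence evidence data.frame from [map_psms()].
#' @return data.frame with `isoform_id`, `group_id`, `anchor` (logical).
#' @export
group_proteins <- function(evidence) {
  n <- nrow(evidence)
  if (!n) {
    return(data.frame(isoform_id = character(), group_id = integer(),
                      anchor = logical(), stringsAsFactors = FALSE))
  }
  sets <- lapply(evidence$detail, function(d) unique(chartr("I", "L", d$backbone)))
  size <- lengths(sets)
  ord <- order(-size, -evidence$protein_score)
  group <- rep(NA_integer_, n)
  anchors <- integer()
  for (i in ord) {
    assigned <- FALSE
    for (g in seq_along(anchors)) {
      if (all(sets[[i]] %in% sets[[anchors[g]]])) {
        group[i] <- g
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      anchors <- c(anchors, i)
      group[i] <- length(anchors)
    }
  }
  data.frame(isoform_id = evidence$isoform_id,
             group_id = group,
             anchor = seq_len(n) %in% anchors,
             stringsAsFactors = FALSE)
}
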