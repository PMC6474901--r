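# Candidate selection: score filters, homology-based contaminant removal,
# signal-peptide gating and family representatives.

#' Acceptance thresholds for byssal-protein candidates
#'
#' Defaults follow the study's acceptance criteria: peptide -10lgP >= 15,
#' protein -10lgP >= 50, de novo average local confidence (ALC) >= 80%, at
#' least 2 peptide spectra, and a BLAST expect value strictly below 1e-6 for
#' contaminant calls.
#'
#' @param min_peptide_score,min_protein_score -10lgP thresholds.
#' @param min_alc_pct ALC threshold (%) for de-novo-only peptides.
#' @param min_spectra minimum qualifying spectra per protein.
#' @param contaminant_evalue_max expect-value cutoff (reject strictly below).
#' @return list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(min_peptide_score = 15, min_protein_score = 50,
                                 min_alc_pct = 80, min_spectra = 2L,
                                 contaminant_evalue_max = 1e-6) {
  stopifnot(min_peptide_score > 0, min_protein_score > 0,
            min_alc_pct > 0, min_alc_pct <= 100,
            min_spectra > 0, contaminant_evalue_max > 0)
  structure(list(min_peptide_score = min_peptide_score,
                 min_protein_score = min_protein_score,
                 min_alc_pct = min_alc_pct,
                 min_spectra = as.integer(min_spectra),
                 contaminant_evalue_max = contaminant_evalue_max),
            class = "selection_thresholds")
}

#' Apply the score-based acceptance criteria to protein evidence
#'
#' A protein is kept iff its protein score meets `min_protein_score` and it
#' has at least `min_spectra` qualifying spectra. Qualifying spectra are PSMs
#' with peptide score >= `min_peptide_score`; de-novo-only PSMs must in
#' addition have ALC >= `min_alc_pct` and, by default, never count toward
#' `min_spectra` (they are tabulated separately upstream). Isoforms listed in
#' `overrides` bypass the score gates and are flagged, mirroring the study's
#' manually justified inclusions.
#'
#' @param evidence evidence data.frame from [map_psms()].
#' @param thresholds a [selection_thresholds()] object.
#' @param overrides character vector of isoform ids to accept regardless.
#' @param count_de_novo also count qualifying de-novo-only spectra toward
#'   `min_spectra` (default FALSE).
#' @return list with `accepted` (evidence rows, plus `override` flag and
#'   `n_qualifying` count) and `rejected` (rows plus a machine-readable
#'   `reason`).
#' @export
apply_score_filters <- function(evidence, thresholds = selection_thresholds(),
                                overrides = character(),
                                count_de_novo = FALSE) {
  n <- nrow(evidence)
  keep <- logical(n); reason <- character(n); nqual <- integer(n)
  for (i in seq_len(n)) {
    det <- evidence$detail[[i]]
    det <- det[!duplicated(det$psm_row), , drop = FALSE]
    db_ok <- !det$is_de_novo_only & det$peptide_score >= thresholds$min_peptide_score
    dn_ok <- det$is_de_novo_only &
      det$peptide_score >= thresholds$min_peptide_score &
      !is.na(det$alc) & det$alc >= thresholds$min_alc_pct
    nqual[i] <- sum(db_ok) + if (count_de_novo) sum(dn_ok) else 0L
    if (is.na(evidence$protein_score[i])) {
      reason[i] <- "unscored"
    } else if (evidence$protein_score[i] < thresholds$min_protein_score) {
      reason[i] <- "low_protein_score"
    } else if (nqual[i] < thresholds$min_spectra) {
      reason[i] <- "insufficient_spectra"
    } else {
      keep[i] <- TRUE
    }
  }
  override <- evidence$isoform_id %in% overrides & !keep
  keep <- keep | override
  accepted <- evidence[keep, , drop = FALSE]
  accepted$override <- override[keep]
  accepted$n_qualifying <- nqual[keep]
  rejected <- evidence[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(accepted = accepted, rejected = rejected)
}

#' Read a 12-column tabular local-alignment (BLAST outfmt 6) hit table
#'
#' @param path hit table path (query, subject, identity, length, mismatches,
#'   gapopens, qstart, qend, sstart, send, evalue, bitscore).
#' @param classes optional sidecar data.frame or TSV path mapping
#'   `subject_id` to `subject_class` (one of `contaminant_db`,
#'   `byssal_allowlist`, `other`); unlisted subjects are classed `other`.
#' @return data.frame with `query_id`, `subject_id`, `evalue`,
#'   `subject_class`.
#' @export
read_homology_hits <- function(path, classes = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) {
    stop("hit table must have the 12 standard tabular columns", call. = FALSE)
  }
  hits <- data.frame(query_id = as.character(df[[1]]),
                     subject_id = as.character(df[[2]]),
                     evalue = as.numeric(df[[11]]),
                     stringsAsFactors = FALSE)
  if (is.character(classes)) classes <- utils::read.delim(classes, stringsAsFactors = FALSE)
  if (is.null(classes)) {
    hits$subject_class <- "other"
  } else {
    idx <- match(hits$subject_id, classes$subject_id)
    hits$subject_class <- ifelse(is.na(idx), "other", classes$subject_class[idx])
  }
  hits
}

#' Remove proteins with strong homology to known cellular contaminants
#'
#' A protein is rejected iff its best hit against the contaminant database
#' has an expect value strictly below the cutoff (`evalue < 1e-6` by
#' default, reading "below e-6" literally). Hits to the byssal allowlist
#' never reject: strong homology to known byssal proteins of related species
#' is expected and is the basis of the protein naming. Proteins with no hits
#' are retained.
#'
#' @param evidence evidence data.frame whose `isoform_id` (or `query_id`
#'   column if present) keys into the hit table's `query_id`.
#' @param hits data.frame from [read_homology_hits()].
#' @param thresholds a [selection_thresholds()] object.
#' @return list with `retained` and `rejected` (with `reason` and
#'   `best_evalue`).
#' @export
contaminant_filter <- function(evidence, hits,
                               thresholds = selection_thresholds()) {
  if (any(hits$evalue < 0)) stop("negative expect value in hit table", call. = FALSE)
  key <- if ("query_id" %in% names(evidence)) evidence$query_id else evidence$isoform_id
  best <- rep(NA_real_, nrow(evidence))
  reject <- logical(nrow(evidence))
  contam <- hits[hits$subject_class == "contaminant_db", , drop = FALSE]
  for (i in seq_len(nrow(evidence))) {
    h <- contam$evalue[contam$query_id == key[i]]
    if (length(h)) {
      best[i] <- min(h)
      reject[i] <- best[i] < thresholds$contaminant_evalue_max
    }
  }
  rejected <- evidence[reject, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "contaminant_homology"
    rejected$best_evalue <- best[reject]
  }
  list(retained = evidence[!reject, , drop = FALSE], rejected = rejected)
}

#' Lightweight signal-peptide cleavage heuristic
#'
#' A classical n/h/c-region rule standing in for a dedicated predictor:
#' a cleavage site at position `p` (15-35) is a candidate when (a) the first
#' five residues carry non-negative net charge (K/R minus D/E), (b) a
#' hydrophobic core of >= `core_len` residues with mean Kyte-Doolittle
#' hydropathy >= `core_min` lies within positions 3-20, and (c) the residues
#' at -3 and -1 relative to the site are small (`A,G,S,C,T,V`). Candidates
#' are scored as core hydropathy plus a small-residue bonus; ties resolve to
#' the smallest position.
#'
#' @param aa_sequence precursor sequence starting at the translated
#'   N-terminus.
#' @param core_min minimum mean hydropathy of the core (default 1.6).
#' @param core_len hydrophobic core length (default 6).
#' @return list with `cleavage_pos`, `score` and `source = "heuristic"`, or
#'   `NULL` when no site qualifies.
#' @export
predict_signal_heuristic <- function(aa_sequence, core_min = 1.6, core_len = 6L) {
  res <- strsplit(toupper(aa_sequence), "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 18L) return(NULL)
  head5 <- res[seq_len(min(5L, n))]
  if (sum(head5 %in% c("K", "R")) - sum(head5 %in% c("D", "E")) < 0) return(NULL)
  kd <- unname(KYTE_DOOLITTLE[res])
  kd[is.na(kd)] <- 0
  # candidate hydrophobic cores: windows of core_len within positions 3-20
  cores <- NULL
  for (s in 3:(min(20L, n) - core_len + 1L)) {
    m <- mean(kd[s:(s + core_len - 1L)])
    if (m >= core_min) cores <- rbind(cores, c(s = s, end = s + core_len - 1L, m = m))
  }
  if (is.null(cores)) return(NULL)
  small <- c("A", "G", "S", "C", "T", "V")
  best <- NULL
  for (p in 15:min(35L, n - 1L)) {
    if (!(res[p] %in% small) || !(res[p - 2L] %in% small)) next
    bonus <- 0.5 * sum(res[c(p - 2L, p)] %in% c("A", "G", "S"))
    # the core must precede the site; a typical c-region puts the cleavage
    # ~5 residues after the core ends
    ok <- cores[cores[, "end"] <= p - 2L, , drop = FALSE]
    if (!nrow(ok)) next
    score <- max(ok[, "m"] + bonus - 0.4 * abs(p - (ok[, "end"] + 5L)))
    if (is.null(best) || score > best$score) {
      best <- list(cleavage_pos = p, score = score, source = "heuristic")
    }
  }
  best
}

#' Gate candidates on the presence of a signal peptide
#'
#' Only proteins with an N-terminal signal peptide -- the hallmark of a
#' secreted protein -- enter the final candidate list. Annotations are taken
#' in priority order: an annotation file, completion from an intact variant,
#' then the built-in heuristic. Conflicting cleavage sites keep the
#' annotation-file value and log the conflict.
#'
#' @param isoforms data.frame with `isoform_id`, `aa_sequence`, `has_start`,
#'   and optionally `signal_pos`/`signal_source` (e.g. from
#'   [complete_signal_from_variants()]).
#' @param annotations optional data.frame (`isoform_id`, `cleavage_pos`)
#'   from an external predictor run.
#' @param use_heuristic fall back to [predict_signal_heuristic()] (default
#'   TRUE).
#' @return list with `passed` (isoforms plus `signal_pos`, `signal_source`),
#'   `failed` (with `reason = "no_signal_peptide"`), and `conflicts`.
#' @export
signal_peptide_gate <- function(isoforms, annotations = NULL,
                                use_heuristic = TRUE) {
  n <- nrow(isoforms)
  pos <- if ("signal_pos" %in% names(isoforms)) isoforms$signal_pos else rep(NA_integer_, n)
  src <- if ("signal_source" %in% names(isoforms)) isoforms$signal_source else rep(NA_character_, n)
  conflicts <- list()
  for (i in seq_len(n)) {
    ann <- NULL
    if (!is.null(annotations)) {
      j <- which(annotations$isoform_id == isoforms$isoform_id[i])
      if (length(j)) ann <- annotations$cleavage_pos[j[1]]
    }
    if (!is.null(ann) && !is.na(ann)) {
      if (!is.na(pos[i]) && pos[i] != ann) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          isoform_id = isoforms$isoform_id[i], kept = ann, dropped = pos[i],
          dropped_source = src[i], stringsAsFactors = FALSE
        )
      }
      pos[i] <- ann
      src[i] <- "annotation_file"
    } else if (is.na(pos[i]) && use_heuristic && isTRUE(isoforms$has_start[i])) {
      h <- predict_signal_heuristic(isoforms$aa_sequence[i])
      if (!is.null(h) && h$cleavage_pos < nchar(isoforms$aa_sequence[i])) {
        pos[i] <- h$cleavage_pos
        src[i] <- "heuristic"
      }
    }
  }
  isoforms$signal_pos <- pos
  isoforms$signal_source <- src
  ok <- !is.na(pos)
  failed <- isoforms[!ok, , drop = FALSE]
  if (nrow(failed)) failed$reason <- "no_signal_peptide"
  list(passed = isoforms[ok, , drop = FALSE], failed = failed,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else NULL)
}

#' Select the representative isoform of a protein family
#'
#' The representative is either the variant with the highest observed number
#' of spectra or, when counts tie (in particular all-zero), the largest
#' mature variant; remaining ties break lexicographically on the sequence.
#'
#' @param family data.frame with columns `total_spectra`, `mature_mass_kda`,
#'   `aa_sequence`.
#' @param priority order of criteria, default spectra first.
#' @return the index (row number) of the representative.
#' @export
select_representative <- function(family,
                                  priority = c("spectra", "mass")) {
  stopifnot(nrow(family) >= 1L)
  keys <- list(spectra = -family$total_spectra,
               mass = -family$mature_mass_kda)
  ord <- do.call(order, c(unname(keys[priority]), list(family$aa_sequence)))
  ord[1]
}
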