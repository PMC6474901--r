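# End-to-end orchestration: transcripts + PSMs + homology + signal
# annotations -> candidate report, with every filtering decision logged.

#' Run the full fingerprinting pipeline
#'
#' Stages: read/translate the transcriptome, map PSMs onto isoforms, apply
#' the score filters, remove contaminants by homology, gate on signal
#' peptides (annotation file first, then completion from intact variants of
#' the same component, then the heuristic), label variants within each
#' component by decreasing mature mass, pick family representatives, and
#' characterize accepted proteins. The run is deterministic given its
#' inputs; every rejected protein appears in exactly one rejection log with
#' a machine-readable reason.
#'
#' @param transcripts data.frame from [read_transcripts()] or a FASTA path.
#' @param psms PSM data.frame (see [read_psms()]) or a vector of TSV paths.
#' @param hits homology hit data.frame (see [read_homology_hits()]) or path;
#'   optional.
#' @param classes subject-class data.frame or TSV path (used when `hits` is
#'   a path).
#' @param signals data.frame (`isoform_id`, `cleavage_pos`) or TSV path;
#'   optional.
#' @param overrides isoform ids accepted despite failing score gates.
#' @param thresholds a [selection_thresholds()].
#' @param min_aa minimum ORF length (default 30).
#' @param il_equivalent I/L equivalence for matching (default TRUE).
#' @return list of class `byssomap_result` with elements `report`,
#'   `accepted`, `rejected`, `unmatched`, `profiles`, `repeats`, `stats`.
#' @export
run_pipeline <- function(transcripts, psms, hits = NULL, classes = NULL,
                         signals = NULL, overrides = character(),
                         thresholds = selection_thresholds(),
                         min_aa = 30L, il_equivalent = TRUE) {
  if (is.character(transcripts)) transcripts <- read_transcripts(transcripts)
  if (is.character(psms)) {
    psms <- do.call(rbind, lapply(psms, read_psms))
  }
  if (is.character(hits)) hits <- read_homology_hits(hits, classes)
  if (is.character(signals)) {
    signals <- utils::read.delim(signals, stringsAsFactors = FALSE)
  }

  isoforms <- translate_transcripts(transcripts, min_aa = min_aa)
  mapped <- map_psms(psms, isoforms, il_equivalent = il_equivalent)
  evidence <- mapped$evidence

  if (!nrow(evidence)) {
    empty <- empty_report()
    return(structure(list(report = empty, accepted = evidence,
                          rejected = evidence, unmatched = mapped$unmatched,
                          profiles = list(), repeats = NULL,
                          stats = list(n_isoforms = nrow(isoforms),
                                       n_psms = nrow(psms),
                                       n_matched_psms = 0L)),
                     class = "byssomap_result"))
  }

  # attach isoform info to evidence
  m <- match(evidence$isoform_id, isoforms$isoform_id)
  evidence$transcript_id <- isoforms$transcript_id[m]
  evidence$component_id <- isoforms$component_id[m]
  evidence$aa_sequence <- isoforms$aa_sequence[m]
  evidence$has_start <- isoforms$has_start[m]

  rejected_logs <- list()

  sc <- apply_score_filters(evidence, thresholds, overrides = overrides)
  if (nrow(sc$rejected)) rejected_logs[["score"]] <- sc$rejected
  surviving <- sc$accepted

  if (!is.null(hits) && nrow(surviving)) {
    cf <- contaminant_filter(surviving, hits, thresholds)
    if (nrow(cf$rejected)) rejected_logs[["contaminant"]] <- cf$rejected
    surviving <- cf$retained
  }

  # signal annotations + variant-based completion, then the gate
  if (nrow(surviving)) {
    surviving$signal_pos <- NA_integer_
    surviving$signal_source <- NA_character_
    if (!is.null(signals)) {
      sm <- match(surviving$isoform_id, signals$isoform_id)
      surviving$signal_pos <- signals$cleavage_pos[sm]
      surviving$signal_source[!is.na(sm)] <- "annotation_file"
    }
    surviving <- complete_signals_within_components(surviving, isoforms, signals)
    gate <- signal_peptide_gate(surviving, annotations = NULL,
                                use_heuristic = TRUE)
    if (nrow(gate$failed)) rejected_logs[["signal"]] <- gate$failed
    surviving <- gate$passed
  }

  accepted <- surviving
  if (nrow(accepted)) {
    accepted$mature_sequence <- vapply(seq_len(nrow(accepted)), function(i) {
      mature_sequence(accepted$aa_sequence[i], accepted$signal_pos[i])
    }, character(1))
    accepted$mature_mass_kda <- vapply(accepted$mature_sequence, average_mass,
                                       numeric(1), USE.NAMES = FALSE)
    count_cols <- grep("^count_", names(accepted), value = TRUE)
    accepted$total_spectra <- rowSums(accepted[, count_cols, drop = FALSE])
    # recompute coverage on the mature sequence (completion may have shifted
    # coordinates, and the initial pass had no signal annotation)
    accepted$coverage_pct <- vapply(seq_len(nrow(accepted)), function(i) {
      det <- accepted$detail[[i]]
      coverage_over(accepted$mature_sequence[i], unique(det$backbone),
                    il_equivalent)
    }, numeric(1))
    # family = component; variant labels by decreasing mature mass
    accepted$variant_label <- NA_character_
    accepted$representative <- FALSE
    for (comp in unique(accepted$component_id)) {
      rows <- which(accepted$component_id == comp)
      fam <- assign_variant_names(accepted[rows, , drop = FALSE])
      accepted$variant_label[rows] <- fam$variant_label
      rep_idx <- select_representative(accepted[rows, , drop = FALSE])
      accepted$representative[rows[rep_idx]] <- TRUE
    }
  }

  profiles <- list()
  repeat_rows <- list()
  if (nrow(accepted)) {
    for (i in seq_len(nrow(accepted))) {
      prof <- property_profile(accepted$mature_sequence[i])
      profiles[[accepted$isoform_id[i]]] <- prof
      reps <- find_tandem_repeats(accepted$mature_sequence[i])
      if (nrow(reps)) {
        reps$isoform_id <- accepted$isoform_id[i]
        repeat_rows[[length(repeat_rows) + 1L]] <- reps
      }
    }
  }
  repeats <- if (length(repeat_rows)) do.call(rbind, repeat_rows) else NULL

  rejected <- combine_rejections(rejected_logs)
  report <- build_report(accepted, rejected, profiles, repeats)

  count_cols <- grep("^count_", names(evidence), value = TRUE)
  stats <- list(
    n_isoforms = nrow(isoforms),
    n_psms = nrow(psms),
    n_matched_psms = length(unique(unlist(
      lapply(evidence$detail, function(d) d$psm_row)))),
    n_proteins_with_evidence = nrow(evidence),
    n_groups = max(group_proteins(evidence)$group_id),
    n_accepted = nrow(accepted),
    n_rejected = if (is.null(rejected)) 0L else nrow(rejected),
    spectra_per_sample = if (length(count_cols)) {
      colSums(evidence[, count_cols, drop = FALSE])
    } else numeric()
  )

  structure(list(report = report, accepted = accepted, rejected = rejected,
                 unmatched = mapped$unmatched, profiles = profiles,
                 repeats = repeats, stats = stats),
            class = "byssomap_result")
}

coverage_over <- function(seq, backbones, il_equivalent = TRUE) {
  key <- if (il_equivalent) chartr("I", "L", seq) else seq
  covered <- rep(FALSE, nchar(seq))
  for (b in backbones) {
    bk <- if (il_equivalent) chartr("I", "L", b) else b
    at <- gregexpr(bk, key, fixed = TRUE)[[1]]
    if (at[1] == -1L) next
    for (s in at) covered[s:(s + nchar(b) - 1L)] <- TRUE
  }
  100 * sum(covered) / nchar(seq)
}

complete_signals_within_components <- function(surviving, isoforms, signals) {
  need <- which(is.na(surviving$signal_pos) & !surviving$has_start)
  if (!length(need)) return(surviving)
  for (i in need) {
    comp <- surviving$component_id[i]
    donors <- isoforms[isoforms$component_id == comp & isoforms$has_start, ,
                       drop = FALSE]
    if (!is.null(signals)) {
      dm <- match(donors$isoform_id, signals$isoform_id)
      donors$signal_pos <- signals$cleavage_pos[dm]
    } else donors$signal_pos <- NA_integer_
    donors <- donors[!is.na(donors$signal_pos), , drop = FALSE]
    if (!nrow(donors)) next
    fam <- data.frame(
      aa_sequence = c(donors$aa_sequence, surviving$aa_sequence[i]),
      has_start = c(donors$has_start, FALSE),
      signal_pos = c(donors$signal_pos, NA_integer_),
      stringsAsFactors = FALSE
    )
    fam <- suppressWarnings(complete_signal_from_variants(fam))
    k <- nrow(fam)
    if (fam$completed[k]) {
      surviving$aa_sequence[i] <- fam$aa_sequence[k]
      surviving$has_start[i] <- TRUE
      surviving$signal_pos[i] <- fam$signal_pos[k]
      surviving$signal_source[i] <- "variant_completion"
    }
  }
  surviving
}

combine_rejections <- function(logs) {
  if (!length(logs)) return(NULL)
  keep <- c("isoform_id", "transcript_id", "component_id", "protein_score",
            "n_psms", "reason")
  rows <- lapply(logs, function(df) {
    df <- df[, intersect(keep, names(df)), drop = FALSE]
    for (col in setdiff(keep, names(df))) df[[col]] <- NA
    df[, keep, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_report <- function() {
  data.frame(family = character(), name = character(),
             representative = logical(), status = character(),
             reason = character(), mature_len = integer(),
             mw_kda = numeric(), pI = numeric(), category = character(),
             top_molpct = character(), coverage_pct = numeric(),
             nterm_segment_pI = numeric(), cterm_segment_pI = numeric(),
             repeats = character(), stringsAsFactors = FALSE)
}

build_report <- function(accepted, rejected, profiles, repeats) {
  rows <- list()
  if (nrow(accepted)) {
    for (i in seq_len(nrow(accepted))) {
      prof <- profiles[[accepted$isoform_id[i]]]
      top <- sort(prof$molpct[prof$molpct > 0], decreasing = TRUE)
      top <- top[seq_len(min(4L, length(top)))]
      reps <- if (!is.null(repeats)) {
        r <- repeats[repeats$isoform_id == accepted$isoform_id[i], , drop = FALSE]
        if (nrow(r)) paste(sprintf("%sx%d@%d", r$unit, r$copies, r$start),
                           collapse = ";") else ""
      } else ""
      row <- data.frame(
        family = accepted$component_id[i],
        name = paste0(accepted$component_id[i], "_",
                      accepted$variant_label[i]),
        representative = accepted$representative[i],
        status = "accepted",
        reason = "",
        mature_len = prof$mature_len,
        mw_kda = round(prof$avg_mass_kda, 1),
        pI = round(prof$pI, 1),
        category = prof$category,
        top_molpct = paste(sprintf("%s=%.1f", names(top), top), collapse = ";"),
        coverage_pct = round(accepted$coverage_pct[i], 1),
        nterm_segment_pI = round(prof$nterm_segment_pI, 1),
        cterm_segment_pI = round(prof$cterm_segment_pI, 1),
        repeats = reps,
        stringsAsFactors = FALSE
      )
      cc <- grep("^count_", names(accepted), value = TRUE)
      for (s in cc) row[[s]] <- accepted[[s]][i]
      rows[[length(rows) + 1L]] <- row
    }
  }
  acc_df <- if (length(rows)) do.call(rbind, rows) else empty_report()
  if (!is.null(rejected) && nrow(rejected)) {
    rej_df <- empty_report()[seq_len(0), , drop = FALSE]
    for (i in seq_len(nrow(rejected))) {
      r <- empty_report()
      r[1, ] <- NA
      r$family <- rejected$component_id[i]
      r$name <- rejected$isoform_id[i]
      r$representative <- FALSE
      r$status <- "rejected"
      r$reason <- rejected$reason[i]
      rej_df <- rbind(rej_df, r)
    }
    for (s in setdiff(names(acc_df), names(rej_df))) rej_df[[s]] <- NA
    for (s in setdiff(names(rej_df), names(acc_df))) acc_df[[s]] <- NA
    out <- rbind(acc_df, rej_df)
  } else out <- acc_df
  rownames(out) <- NULL
  out
}

#' Write pipeline outputs as TSV artifacts
#'
#' @param result a `byssomap_result` from [run_pipeline()].
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  f <- file.path(dir, "report.tsv")
  utils::write.table(result$report, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  if (!is.null(result$rejected) && nrow(result$rejected)) {
    f <- file.path(dir, "rejected.tsv")
    utils::write.table(result$rejected, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  if (nrow(result$unmatched)) {
    f <- file.path(dir, "unmatched_psms.tsv")
    utils::write.table(result$unmatched, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(result$repeats)) {
    f <- file.path(dir, "repeats.tsv")
    utils::write.table(result$repeats, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
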