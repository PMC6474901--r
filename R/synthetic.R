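# Seeded synthetic datasets with planted ground truth: a toy assembled
# transcriptome, PSM tables, homology hits and signal annotations, shaped
# like the study inputs (four MS samples, gel-band mass windows, variant
# families, cellular contaminants).

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the study conditions: mature masses in 4-22 kDa, four
#' samples (`whole_TP` plus the ~6, ~7 and ~14 kDa gel bands with SDS-PAGE
#' band clipping), peptide scores straddling the -10lgP 15 threshold
#' (true ~ Normal(35, 8) truncated at 0, noise ~ Normal(10, 5)), protein
#' scores above 50 for planted secreted proteins and for contaminants (so
#' that contaminant removal is exercised by the homology filter, not the
#' score filter), and tandem repeats planted from the library of published
#' byssal repeat units.
#'
#' @param n_families number of planted secreted protein families.
#' @param variants_per_family variants per family (Greek-letter polymorphs).
#' @param n_contaminants planted cellular contaminants (no signal peptide,
#'   strong homology hit).
#' @param n_decoys residue-shuffled de-novo-only noise peptides.
#' @param mass_range_kda mature-mass range of planted proteins.
#' @param repeat_library list of `list(unit, copies)` planted cyclically
#'   into families.
#' @param band_windows per-band mature-mass windows in kDa.
#' @param mod_prob probability that a PSM carries a deamidation or
#'   hydroxylation mark.
#' @param truncate_first_family emit the first family's last variant as a
#'   5'-truncated transcript (no start codon, partial signal) to exercise
#'   variant-based signal completion.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_families = 4L, variants_per_family = 2L,
                             n_contaminants = 3L, n_decoys = 15L,
                             mass_range_kda = c(4, 22),
                             repeat_library = list(
                               list(unit = "PKYPGGGN", copies = 4L),
                               list(unit = "YPTYPEKK", copies = 5L),
                               list(unit = "GNYG", copies = 3L)
                             ),
                             band_windows = list(
                               band6 = c(4.5, 7.5),
                               band7 = c(5.5, 8.5),
                               band14 = c(11, 17)
                             ),
                             mod_prob = 0.1,
                             truncate_first_family = TRUE) {
  stopifnot(n_families >= 1L, variants_per_family >= 1L,
            mass_range_kda[1] < mass_range_kda[2])
  structure(as.list(environment()), class = "synthetic_config")
}

# byssal-flavoured residue frequencies for mature regions (G/Y/P/N heavy,
# K/R guarantee tryptic sites)
BYSSAL_FREQ <- c(G = 0.16, Y = 0.11, P = 0.10, N = 0.08, S = 0.08, K = 0.08,
                 R = 0.06, D = 0.06, A = 0.06, Q = 0.05, T = 0.05, V = 0.04,
                 E = 0.03, C = 0.03, W = 0.02, F = 0.02, L = 0.03, I = 0.02,
                 H = 0.01, M = 0.01)

random_mature <- function(len) {
  paste(sample(names(BYSSAL_FREQ), len, replace = TRUE, prob = BYSSAL_FREQ),
        collapse = "")
}

# mean residue mass of the byssal-flavoured alphabet, for length targeting
BYSSAL_MEAN_RESIDUE <- sum(BYSSAL_FREQ * AA_AVERAGE_MASS[names(BYSSAL_FREQ)])

# nudge a mature sequence into the configured mass window: trim the random
# tail when too heavy, extend it when too light
fit_mass_window <- function(mat, lo, hi) {
  while (average_mass(mat) > hi && nchar(mat) > 40L) {
    mat <- substr(mat, 1L, nchar(mat) - 1L)
  }
  while (average_mass(mat) < lo) {
    mat <- paste0(mat, random_mature(3L))
  }
  mat
}

random_signal <- function() {
  n_region <- paste0("M", paste(sample(c("K", "R"), sample(1:2, 1),
                                       replace = TRUE), collapse = ""))
  h_core <- paste(sample(c("L", "A", "V", "I", "F"), sample(9:11, 1),
                         replace = TRUE, prob = c(0.35, 0.25, 0.2, 0.12, 0.08)),
                  collapse = "")
  c_region <- paste0(paste(sample(c("S", "T", "G"), 2, replace = TRUE),
                           collapse = ""),
                     "A", sample(c("S", "Q", "H"), 1), "A")
  paste0(n_region, h_core, c_region)
}

#' Simulate a planted proteome
#'
#' Builds secreted protein families (each with a signal peptide that
#' satisfies the built-in heuristic, Greek-letter variants created by seeded
#' internal deletions, and optionally a planted tandem repeat) plus
#' cytosolic-style contaminants without signal peptides.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; outputs are fully determined by
#'   `(config, seed)`.
#' @return list of class `synthetic_truth` with `proteins` (data.frame),
#'   `config`, `seed`.
#' @export
simulate_proteome <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  lo <- config$mass_range_kda[1]; hi <- config$mass_range_kda[2]
  max_len <- floor((hi * 1000 - 18) / BYSSAL_MEAN_RESIDUE)
  for (r in config$repeat_library) {
    if (nchar(r$unit) * r$copies > max_len - 20L) {
      stop("infeasible config: planted repeat '", r$unit, "' x", r$copies,
           " does not fit the mass range", call. = FALSE)
    }
  }
  rows <- list()
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("SynFp%02d", f)
    signal <- random_signal()
    mass <- stats::runif(1, lo + 0.2 * (hi - lo), hi - 1)
    len <- max(40L, round((mass * 1000 - 18) / BYSSAL_MEAN_RESIDUE))
    rep_spec <- config$repeat_library[[(f - 1L) %% length(config$repeat_library) + 1L]]
    planted <- strrep(rep_spec$unit, rep_spec$copies)
    fill <- len - nchar(planted)
    pre <- random_mature(max(5L, fill %/% 2L))
    post <- random_mature(max(5L, fill - fill %/% 2L))
    mature1 <- paste0(pre, "K", planted, "R", post)
    for (v in seq_len(config$variants_per_family)) {
      mat <- mature1
      if (v > 1L) {
        # seeded internal deletion after the planted repeat block
        del_len <- sample(8:18, 1) * (v - 1L)
        anchor <- nchar(pre) + 2L + nchar(planted) + 2L
        avail <- nchar(mat) - anchor - 10L
        del_len <- min(del_len, max(0L, avail))
        if (del_len > 0L) {
          mat <- paste0(substr(mat, 1L, anchor - 1L),
                        substring(mat, anchor + del_len))
        }
        # a couple of substitutions to mimic allelic variation, placed
        # beyond the N-terminal overlap window used for signal completion
        res <- strsplit(mat, "", fixed = TRUE)[[1]]
        lo_sub <- 13L
        hi_sub <- nchar(pre) %/% 2L + 12L
        if (hi_sub > lo_sub) {
          at <- sample(lo_sub:hi_sub, 2L)
          res[at] <- sample(c("G", "S", "N", "A"), length(at), replace = TRUE)
        }
        mat <- paste(res, collapse = "")
      }
      mat <- fit_mass_window(mat, lo, hi)
      truncated <- config$truncate_first_family && f == 1L &&
        v == config$variants_per_family && config$variants_per_family > 1L
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(fam, "_v", v), family = fam, variant_idx = v,
        signal = signal, mature = mat,
        precursor = paste0(signal, mat),
        cleavage_pos = nchar(signal),
        mature_mass_kda = average_mass(mat),
        is_contaminant = FALSE,
        repeat_unit = rep_spec$unit, repeat_copies = rep_spec$copies,
        truncated = truncated, stringsAsFactors = FALSE
      )
    }
  }
  for (k in seq_len(config$n_contaminants)) {
    len <- sample(90:180, 1)
    # polar/charged composition, deliberately without a hydrophobic core
    mat <- paste(sample(c("D", "E", "K", "R", "S", "T", "G", "N", "Q", "P"),
                        len, replace = TRUE), collapse = "")
    mat <- paste0("M", mat)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("Contam%02d", k), family = sprintf("Contam%02d", k),
      variant_idx = 1L, signal = "", mature = mat, precursor = mat,
      cleavage_pos = NA_integer_, mature_mass_kda = average_mass(mat),
      is_contaminant = TRUE, repeat_unit = NA_character_,
      repeat_copies = NA_integer_, truncated = FALSE,
      stringsAsFactors = FALSE
    )
  }
  proteins <- do.call(rbind, rows)
  rownames(proteins) <- NULL
  structure(list(proteins = proteins, config = config, seed = seed),
            class = "synthetic_truth")
}

CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  split(codons, aa)
})

#' Reverse-translate a protein into a synthetic transcript
#'
#' Uniform seeded codon choice, plus seeded UTRs; the 5' UTR ends with an
#' in-frame stop codon so the encoded ORF begins exactly at the start Met.
#' Optionally the transcript is emitted 5'-truncated (starting mid-signal,
#' without the start codon) or on the reverse strand.
#'
#' @param aa_sequence protein sequence to encode.
#' @param truncate_from 1-based residue at which a truncated transcript
#'   starts, or `NA` for a complete one.
#' @param reverse_strand emit the reverse complement.
#' @param utr_max maximum UTR length in nt.
#' @return nucleotide string.
#' @export
reverse_translate <- function(aa_sequence, truncate_from = NA_integer_,
                              reverse_strand = FALSE, utr_max = 60L) {
  residues <- strsplit(aa_sequence, "", fixed = TRUE)[[1]]
  if (!is.na(truncate_from)) residues <- residues[truncate_from:length(residues)]
  codons <- vapply(residues, function(a) {
    opts <- CODON_TABLE[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  cds <- paste(codons, collapse = "")
  utr3 <- paste(sample(c("A", "C", "G", "T"), sample(0:utr_max, 1),
                       replace = TRUE), collapse = "")
  utr5 <- if (is.na(truncate_from)) {
    k <- sample(0:(utr_max %/% 3 - 1L), 1)
    paste0(paste(sample(c("A", "C", "G", "T"), 3L * k, replace = TRUE),
                 collapse = ""), "TAA")
  } else ""
  stopc <- CODON_TABLE[["*"]][sample.int(3L, 1L)]
  dna <- paste0(utr5, cds, stopc, utr3)
  if (reverse_strand) {
    dna <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  }
  dna
}

truncated_nterm_start <- function(cleavage_pos) {
  # keep roughly the C-terminal half of the signal so >=10 aa of exact
  # overlap with the intact variant remains for completion
  max(2L, cleavage_pos - 9L)
}

#' Simulate the full synthetic dataset
#'
#' Generates the planted proteome, its transcriptome (one transcript per
#' variant, Trinity-style ids, family variants sharing a component), locates
#' each planted protein in the package's own six-frame translation to key
#' the signal-annotation table, and simulates PSM, homology-hit and
#' subject-class tables.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list of class `synthetic_dataset`: `truth`, `transcripts`,
#'   `isoform_index` (planted protein -> isoform), `psms`, `hits`,
#'   `classes`, `signals`.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1L) {
  truth <- simulate_proteome(config, seed)
  pr <- truth$proteins

  set.seed(seed + 1L)
  tx_rows <- lapply(seq_len(nrow(pr)), function(i) {
    p <- pr[i, ]
    comp <- if (p$is_contaminant) {
      sprintf("comp%d_c0", 90000L + i)
    } else {
      sprintf("comp%d_c0", 10000L + match(p$family, unique(pr$family)))
    }
    trunc_from <- if (p$truncated) truncated_nterm_start(p$cleavage_pos) else NA_integer_
    data.frame(
      id = sprintf("%s_seq%d", comp, p$variant_idx),
      component_id = comp,
      sequence = reverse_translate(p$precursor, truncate_from = trunc_from,
                                   reverse_strand = stats::runif(1) < 0.5),
      stringsAsFactors = FALSE
    )
  })
  transcripts <- do.call(rbind, tx_rows)
  transcripts$length_bp <- nchar(transcripts$sequence)

  # locate every planted protein in the package's own translation so that
  # annotation tables are keyed exactly like pipeline isoforms
  isoforms <- translate_transcripts(transcripts, min_aa = 30L)
  idx <- lapply(seq_len(nrow(pr)), function(i) {
    p <- pr[i, ]
    expect <- if (p$truncated) {
      substring(p$precursor, truncated_nterm_start(p$cleavage_pos))
    } else p$precursor
    cand <- isoforms[isoforms$transcript_id == transcripts$id[i], , drop = FALSE]
    hit <- which(vapply(cand$aa_sequence, function(s) {
      grepl(expect, s, fixed = TRUE)
    }, logical(1)))[1]
    if (is.na(hit)) {
      stop("internal: planted protein ", p$name, " not recovered by translation",
           call. = FALSE)
    }
    offset <- as.integer(regexpr(expect, cand$aa_sequence[hit], fixed = TRUE)) - 1L
    data.frame(name = p$name, isoform_id = cand$isoform_id[hit],
               transcript_id = transcripts$id[i],
               cleavage_in_orf = if (p$is_contaminant || p$truncated) NA_integer_
                                 else offset + p$cleavage_pos,
               stringsAsFactors = FALSE)
  })
  isoform_index <- do.call(rbind, idx)

  signals <- isoform_index[!is.na(isoform_index$cleavage_in_orf),
                           c("isoform_id", "cleavage_in_orf")]
  names(signals) <- c("isoform_id", "cleavage_pos")
  rownames(signals) <- NULL

  # homology tables: contaminants hit the contaminant DB strongly; secreted
  # families get allowlist hits to related-species byssal proteins
  set.seed(seed + 2L)
  hit_rows <- list()
  class_rows <- list(
    data.frame(subject_id = "cellular_actin_like", subject_class = "contaminant_db"),
    data.frame(subject_id = "Dpfp_homolog", subject_class = "byssal_allowlist")
  )
  for (i in seq_len(nrow(pr))) {
    if (pr$is_contaminant[i]) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_id = isoform_index$isoform_id[i], subject_id = "cellular_actin_like",
        evalue = 10^-stats::runif(1, 10, 40), stringsAsFactors = FALSE
      )
    } else if (pr$variant_idx[i] == 1L && stats::runif(1) < 0.5) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_id = isoform_index$isoform_id[i], subject_id = "Dpfp_homolog",
        evalue = 10^-stats::runif(1, 20, 70), stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(query_id = character(), subject_id = character(),
               evalue = numeric(), stringsAsFactors = FALSE)
  classes <- do.call(rbind, class_rows)
  if (nrow(hits)) {
    hits$subject_class <- classes$subject_class[match(hits$subject_id,
                                                      classes$subject_id)]
  } else hits$subject_class <- character()

  psms <- simulate_psms(truth, isoform_index, config, seed + 3L)

  structure(list(truth = truth, transcripts = transcripts,
                 isoform_index = isoform_index, psms = psms, hits = hits,
                 classes = classes, signals = signals),
            class = "synthetic_dataset")
}

rtrunc_norm <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) {
    x[x < lower] <- stats::rnorm(sum(x < lower), mean, sd)
  }
  x
}

apply_mod_mark <- function(peptide, prob) {
  if (stats::runif(1) >= prob) return(peptide)
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  at <- which(res %in% c("N", "Q", "Y"))
  if (!length(at)) return(peptide)
  pick <- at[sample.int(length(at), 1L)]
  res[pick] <- tolower(res[pick])
  paste(res, collapse = "")
}

#' Simulate PSM tables for a planted proteome
#'
#' True peptides are drawn from tryptic digests of the planted matures;
#' every planted secreted protein receives at least two `whole_TP` spectra
#' with peptide score >= 20, so the planted truth is recoverable under the
#' acceptance thresholds. Gel-band samples only receive PSMs from proteins
#' whose mature mass lies within the band's window (SDS-PAGE clipping).
#' Contaminants receive passing protein scores, so only the homology filter
#' can remove them. Decoy noise is residue-shuffled (re-shuffled on
#' collision with any planted precursor), flagged de-novo-only.
#'
#' @param truth a `synthetic_truth`.
#' @param isoform_index data.frame mapping planted proteins to isoform and
#'   transcript ids (from [simulate_dataset()]).
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return PSM data.frame with the standard columns.
#' @export
simulate_psms <- function(truth, isoform_index, config, seed) {
  set.seed(seed)
  pr <- truth$proteins
  dp <- digest_params(missed_cleavages = 1L, min_len = 6L, max_len = 30L)
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  il_keys <- chartr("I", "L", pr$precursor)
  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    peps <- digest(p$mature, dp)
    peps <- peps[!grepl("X", peps$peptide, fixed = TRUE), , drop = FALSE]
    if (nrow(peps) < 2L) {
      stop("infeasible config: planted protein ", p$name,
           " yields fewer than 2 tryptic peptides", call. = FALSE)
    }
    protein_score <- if (p$is_contaminant) stats::runif(1, 52, 75)
                     else stats::runif(1, 55, 110)
    tid <- isoform_index$transcript_id[isoform_index$name == p$name]
    emit <- function(sample_name, n, min_score = 0) {
      if (n <= 0L) return(invisible())
      pep <- peps$peptide[sample.int(nrow(peps), n, replace = TRUE)]
      score <- rtrunc_norm(n, 35, 8, lower = min_score)
      pep <- vapply(pep, apply_mod_mark, character(1), prob = config$mod_prob,
                    USE.NAMES = FALSE)
      add(data.frame(sample = sample_name, peptide = pep,
                     peptide_score = round(score, 2), alc = NA_real_,
                     is_de_novo_only = FALSE,
                     protein_score = round(protein_score, 2),
                     transcript_hint = tid, stringsAsFactors = FALSE))
    }
    # guaranteed high-score evidence in the whole thread/plaque extract
    emit("whole_TP", 2L, min_score = 20)
    emit("whole_TP", stats::rpois(1, 2))
    for (band in names(config$band_windows)) {
      w <- config$band_windows[[band]]
      if (p$mature_mass_kda >= w[1] && p$mature_mass_kda <= w[2]) {
        emit(band, stats::rpois(1, 1.5))
      }
    }
  }
  # decoys: shuffled true peptides, never matching any planted precursor
  all_peps <- unlist(lapply(pr$mature, function(m) digest(m, dp)$peptide))
  for (d in seq_len(config$n_decoys)) {
    src <- all_peps[sample.int(length(all_peps), 1L)]
    for (try in 1:50) {
      dec <- paste(sample(strsplit(src, "", fixed = TRUE)[[1]]), collapse = "")
      if (!any(grepl(chartr("I", "L", dec), il_keys, fixed = TRUE))) break
    }
    add(data.frame(sample = "whole_TP", peptide = dec,
                   peptide_score = round(rtrunc_norm(1, 10, 5), 2),
                   alc = round(stats::runif(1, 60, 95), 1),
                   is_de_novo_only = TRUE, protein_score = NA_real_,
                   transcript_hint = NA_character_, stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits `transcripts.fasta`, one `psms_<sample>.tsv` per sample,
#' `hits.tsv` (12-column tabular alignment format), `classes.tsv`,
#' `signals.tsv` and `truth.json`. Output is byte-identical for a fixed
#' `(config, seed)`.
#'
#' @param dataset a `synthetic_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  fa <- file.path(dir, "transcripts.fasta")
  writeLines(paste0(">", dataset$transcripts$id, "\n",
                    dataset$transcripts$sequence), fa)
  files <- c(files, fa)
  for (s in unique(dataset$psms$sample)) {
    f <- file.path(dir, paste0("psms_", s, ".tsv"))
    utils::write.table(dataset$psms[dataset$psms$sample == s, , drop = FALSE],
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "hits.tsv")
  h <- dataset$hits
  blast12 <- data.frame(h$query_id, h$subject_id, 100, 50, 0, 0, 1, 50, 1, 50,
                        format(h$evalue, scientific = TRUE, digits = 3), 100)
  utils::write.table(blast12, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "classes.tsv")
  utils::write.table(dataset$classes, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "signals.tsv")
  utils::write.table(dataset$signals, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    f <- file.path(dir, "truth.json")
    jsonlite::write_json(dataset$truth$proteins, f, auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}
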