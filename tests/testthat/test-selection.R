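# Score filters, contaminant removal, signal gating, representatives.

fake_evidence <- function(protein_score, pep_scores, de_novo = FALSE,
                          alc = NA_real_, id = "iso1") {
  det <- data.frame(psm_row = seq_along(pep_scores),
                    peptide = paste0("PEPT", seq_along(pep_scores), "K"),
                    backbone = paste0("PEPT", seq_along(pep_scores), "K"),
                    sample = "whole_TP", peptide_score = pep_scores,
                    alc = alc, is_de_novo_only = de_novo,
                    start = 1L, stringsAsFactors = FALSE)
  ev <- data.frame(isoform_id = id, protein_score = protein_score,
                   n_unique_peptides = length(pep_scores),
                   n_psms = length(pep_scores), coverage_pct = 50,
                   stringsAsFactors = FALSE)
  ev$detail <- I(list(det))
  ev
}

test_that("score gates apply the thresholds at their boundaries", {
  th <- selection_thresholds()
  r1 <- apply_score_filters(fake_evidence(49.9, c(30, 30, 30)), th)
  expect_equal(nrow(r1$accepted), 0L)
  expect_equal(r1$rejected$reason, "low_protein_score")

  r2 <- apply_score_filters(fake_evidence(50, c(30, 30)), th)
  expect_equal(nrow(r2$accepted), 1L)

  r3 <- apply_score_filters(fake_evidence(60, c(30, 14.9)), th)
  expect_equal(r3$rejected$reason, "insufficient_spectra")

  r4 <- apply_score_filters(fake_evidence(NA_real_, c(30, 30)), th)
  expect_equal(r4$rejected$reason, "unscored")
})

test_that("overrides bypass the score gates and are flagged", {
  r <- apply_score_filters(fake_evidence(47.9, c(30, 30), id = "Dbfp17-like"),
                           overrides = "Dbfp17-like")
  expect_equal(nrow(r$accepted), 1L)
  expect_true(r$accepted$override)
})

test_that("de-novo-only spectra need ALC >= 80 and do not count by default", {
  ev <- fake_evidence(60, c(30, 30), de_novo = TRUE, alc = 85)
  r <- apply_score_filters(ev)
  expect_equal(r$rejected$reason, "insufficient_spectra")
  r2 <- apply_score_filters(ev, count_de_novo = TRUE)
  expect_equal(nrow(r2$accepted), 1L)
  # low ALC disqualifies even when counted
  ev_low <- fake_evidence(60, c(30, 30), de_novo = TRUE, alc = 70)
  r3 <- apply_score_filters(ev_low, count_de_novo = TRUE)
  expect_equal(nrow(r3$accepted), 0L)
})

test_that("the accepted set equals an independent predicate over random evidence", {
  set.seed(41)
  th <- selection_thresholds()
  evs <- lapply(1:200, function(i) {
    n <- sample(1:5, 1)
    fake_evidence(runif(1, 30, 80), runif(n, 5, 45), id = paste0("iso", i))
  })
  evidence <- do.call(rbind, evs)
  res <- apply_score_filters(evidence, th)
  want <- vapply(seq_len(nrow(evidence)), function(i) {
    det <- evidence$detail[[i]]
    evidence$protein_score[i] >= 50 && sum(det$peptide_score >= 15) >= 2
  }, logical(1))
  expect_setequal(res$accepted$isoform_id, evidence$isoform_id[want])
})

test_that("contaminant homology rejects strictly below e-6 and spares the allowlist", {
  ev <- do.call(rbind, lapply(paste0("iso", 1:4),
                              function(id) fake_evidence(60, c(30, 30), id = id)))
  hits <- data.frame(
    query_id = c("iso1", "iso2", "iso3"),
    subject_id = c("actin_like", "Dpfp5", "actin_like"),
    evalue = c(1e-7, 2e-66, 1e-5),
    subject_class = c("contaminant_db", "byssal_allowlist", "contaminant_db"),
    stringsAsFactors = FALSE
  )
  r <- contaminant_filter(ev, hits)
  expect_setequal(r$rejected$isoform_id, "iso1")
  expect_setequal(r$retained$isoform_id, c("iso2", "iso3", "iso4"))
  hits$evalue[1] <- -1
  expect_error(contaminant_filter(ev, hits), "negative")
})

test_that("the signal heuristic finds a classical cleavage site and rejects non-signals", {
  h <- predict_signal_heuristic("MKWVTFISLLFLFSSAYSRGVFRRDAHKSEVAHRFKDLGE")
  expect_false(is.null(h))
  expect_true(abs(h$cleavage_pos - 18) <= 3)
  expect_null(predict_signal_heuristic(strrep("MDDDDDDDDDD", 4)))
})

test_that("the heuristic recovers most curated cleavage sites within +/-3", {
  pre <- dbfp_precursors()
  pre <- pre[!is.na(pre$cleavage_pos), ]
  ok <- vapply(seq_len(nrow(pre)), function(i) {
    h <- predict_signal_heuristic(pre$sequence[i])
    !is.null(h) && abs(h$cleavage_pos - pre$cleavage_pos[i]) <= 3
  }, logical(1))
  # documented accuracy of the n/h/c + (-3,-1) rule on this set
  expect_gte(sum(ok), 11L)
  expect_equal(length(ok), 15L)
})

test_that("the signal gate prefers annotations, then completion, then heuristic", {
  isoforms <- data.frame(
    isoform_id = c("a", "b", "c"),
    aa_sequence = c("MKWVTFISLLFLFSSAYSRGVFRRDAHKSEVAHRFKDLGE",
                    "MKWVTFISLLFLFSSAYSRGVFRRDAHKSEVAHRFKDLGE",
                    strrep("GGDDEE", 10)),
    has_start = c(TRUE, TRUE, FALSE),
    signal_pos = c(17L, NA_integer_, NA_integer_),
    signal_source = c("variant_completion", NA, NA),
    stringsAsFactors = FALSE
  )
  ann <- data.frame(isoform_id = "a", cleavage_pos = 19L)
  r <- signal_peptide_gate(isoforms, annotations = ann)
  a <- r$passed[r$passed$isoform_id == "a", ]
  expect_equal(a$signal_pos, 19L)           # annotation wins
  expect_equal(a$signal_source, "annotation_file")
  expect_equal(nrow(r$conflicts), 1L)
  b <- r$passed[r$passed$isoform_id == "b", ]
  expect_equal(b$signal_source, "heuristic")
  expect_equal(r$failed$isoform_id, "c")
  expect_equal(r$failed$reason, "no_signal_peptide")
})

test_that("representative selection follows spectra then mature mass", {
  fam <- data.frame(total_spectra = c(0, 6), mature_mass_kda = c(6.6, 5.6),
                    aa_sequence = c("AAA", "BBB"))
  expect_equal(select_representative(fam), 2L)   # spectra win

  zero <- data.frame(total_spectra = c(0, 0), mature_mass_kda = c(6.6, 5.6),
                     aa_sequence = c("AAA", "BBB"))
  expect_equal(select_representative(zero), 1L)  # heaviest variant

  set.seed(42)
  for (rep in 1:10) {
    fam <- data.frame(total_spectra = sample(0:5, 6, replace = TRUE),
                      mature_mass_kda = runif(6, 4, 22),
                      aa_sequence = replicate(6, random_aa(8)))
    got <- select_representative(fam)
    want <- order(-fam$total_spectra, -fam$mature_mass_kda, fam$aa_sequence)[1]
    expect_equal(got, want)
  }
})

test_that("score, contaminant and signal filters commute", {
  set.seed(43)
  ids <- paste0("iso", 1:12)
  evs <- do.call(rbind, lapply(ids, function(id) {
    ev <- fake_evidence(runif(1, 40, 80), runif(3, 10, 45), id = id)
    ev$aa_sequence <- paste0("MKWVTFISLLFLFSSAYSRGVFRR", random_aa(20))
    ev$has_start <- TRUE
    ev
  }))
  hits <- data.frame(query_id = sample(ids, 4), subject_id = "actin_like",
                     evalue = 10^-runif(4, 3, 12),
                     subject_class = "contaminant_db", stringsAsFactors = FALSE)
  run_order <- function(orders) {
    surv <- evs
    for (step in orders) {
      if (!nrow(surv)) break
      surv <- switch(step,
        score = apply_score_filters(surv)$accepted,
        contaminant = contaminant_filter(surv, hits)$retained,
        signal = signal_peptide_gate(surv)$passed)
    }
    sort(surv$isoform_id)
  }
  o1 <- run_order(c("score", "contaminant", "signal"))
  o2 <- run_order(c("signal", "score", "contaminant"))
  o3 <- run_order(c("contaminant", "signal", "score"))
  expect_equal(o1, o2)
  expect_equal(o1, o3)
})
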