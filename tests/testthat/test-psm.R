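# Modification keys, PSM-to-isoform mapping, spectral counting, grouping.

make_psm <- function(peptide, sample = "whole_TP", score = 35, alc = NA_real_,
                     de_novo = FALSE, protein_score = NA_real_,
                     hint = NA_character_) {
  data.frame(sample = sample, peptide = peptide, peptide_score = score,
             alc = alc, is_de_novo_only = de_novo,
             protein_score = protein_score, transcript_hint = hint,
             stringsAsFactors = FALSE)
}

iso_df <- function(seqs, signal = NA_integer_) {
  data.frame(isoform_id = paste0("iso", seq_along(seqs)),
             transcript_id = paste0("t", seq_along(seqs)),
             aa_sequence = seqs, signal_pos = signal,
             stringsAsFactors = FALSE)
}

test_that("modification marks resolve to the plain backbone and are recorded", {
  plain <- expand_modification_keys("GGSDDPPAAPGR")
  expect_equal(plain$backbone, "GGSDDPPAAPGR")
  expect_equal(nrow(plain$mods), 0L)

  deam <- expand_modification_keys("RVCRPnECYVGR")
  expect_equal(deam$backbone, "RVCRPNECYVGR")
  expect_equal(deam$mods$pos, 6L)
  expect_equal(deam$mods$type, "deamidation")

  hyd <- expand_modification_keys("yLGGGN")
  expect_equal(hyd$backbone, "YLGGGN")
  expect_equal(hyd$mods$type, "hydroxylation")

  expect_error(expand_modification_keys("GGsDD"), "mark")
})

test_that("mapped peptides cover the mature sequence correctly", {
  res <- map_psms(make_psm("AAAKW"), iso_df("MAAAKWGGGG", signal = 1L))
  ev <- res$evidence
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$coverage_pct, 100 * 5 / 9)
  expect_equal(ev$n_unique_peptides, 1L)
})

test_that("per-sample spectral counts follow the sample labels", {
  psms <- do.call(rbind, lapply(c("whole_TP", "band6", "band7", "band14"),
                                function(s) make_psm("AAAKW", sample = s)))
  ev <- map_psms(psms, iso_df("MAAAKWGGGG"))$evidence
  expect_equal(ev$count_whole_TP, 1L)
  expect_equal(ev$count_band6, 1L)
  expect_equal(ev$count_band7, 1L)
  expect_equal(ev$count_band14, 1L)
  expect_equal(ev$n_psms, 4L)
})

test_that("matching agrees with a brute-force all-pairs substring scan", {
  set.seed(31)
  isoforms <- iso_df(replicate(10, random_aa(60)))
  peps <- character(50)
  for (i in 1:50) {
    if (i %% 2 == 0) {
      src <- sample(isoforms$aa_sequence, 1)
      s <- sample(1:50, 1)
      peps[i] <- substr(src, s, s + sample(5:9, 1))
    } else {
      peps[i] <- random_aa(sample(6:10, 1))
    }
  }
  psms <- do.call(rbind, lapply(peps, make_psm))
  res <- map_psms(psms, isoforms, il_equivalent = TRUE)
  for (i in seq_len(nrow(isoforms))) {
    want <- unique(peps[vapply(peps, function(p) {
      grepl(chartr("I", "L", p), chartr("I", "L", isoforms$aa_sequence[i]),
            fixed = TRUE)
    }, logical(1))])
    ev <- res$evidence[res$evidence$isoform_id == isoforms$isoform_id[i], ]
    got <- if (nrow(ev)) unique(ev$detail[[1]]$backbone) else character()
    expect_setequal(got, want)
  }
  # every PSM is either matched somewhere or reported unmatched
  matched <- unique(unlist(lapply(res$evidence$detail, function(d) d$psm_row)))
  expect_setequal(c(matched, as.integer(rownames(res$unmatched))),
                  seq_len(nrow(psms)))
})

test_that("strict I/L matching finds a subset of the equivalent matching", {
  set.seed(32)
  isoforms <- iso_df(replicate(6, random_aa(50)))
  peps <- vapply(1:30, function(i) {
    src <- sample(isoforms$aa_sequence, 1)
    s <- sample(1:40, 1)
    chartr("I", "L", substr(src, s, s + 7))   # force I->L so strict may miss
  }, character(1))
  psms <- do.call(rbind, lapply(peps, make_psm))
  loose <- map_psms(psms, isoforms, il_equivalent = TRUE)$evidence
  strict <- map_psms(psms, isoforms, il_equivalent = FALSE)$evidence
  loose_pairs <- unlist(lapply(seq_len(nrow(loose)), function(i)
    paste(loose$isoform_id[i], loose$detail[[i]]$psm_row)))
  strict_pairs <- unlist(lapply(seq_len(nrow(strict)), function(i)
    paste(strict$isoform_id[i], strict$detail[[i]]$psm_row)))
  expect_true(all(strict_pairs %in% loose_pairs))
})

test_that("coverage is monotone non-decreasing as PSMs accumulate", {
  set.seed(33)
  iso <- iso_df(random_aa(80))
  peps <- vapply(1:8, function(i) {
    s <- sample(1:70, 1); substr(iso$aa_sequence, s, s + 8)
  }, character(1))
  cov <- vapply(1:8, function(k) {
    psms <- do.call(rbind, lapply(peps[1:k], make_psm))
    map_psms(psms, iso)$evidence$coverage_pct
  }, numeric(1))
  expect_true(all(diff(cov) >= -1e-12))
  expect_true(all(cov >= 0 & cov <= 100))
})

test_that("non-tryptic termini are flagged, not rejected", {
  # FVDPTNR preceded by H: N-terminus is non-tryptic
  iso <- iso_df("MKLHFVDPTNRCTS")
  ev <- map_psms(make_psm("FVDPTNR"), iso)$evidence
  expect_equal(nrow(ev), 1L)
  expect_true(ev$detail[[1]]$nontryptic[1])
  # tryptic boundaries are not flagged
  ev2 <- map_psms(make_psm("FVDPTNR"), iso_df("MKFVDPTNRCTS"))$evidence
  expect_false(ev2$detail[[1]]$nontryptic[1])
})

test_that("protein grouping merges subset peptide sets onto the anchor", {
  isoforms <- iso_df(c("AAAAKGGGGRWWWWK", "AAAAKGGGGR"))
  psms <- rbind(make_psm("AAAAK", protein_score = 60, hint = "t1"),
                make_psm("GGGGR", protein_score = 60, hint = "t1"),
                make_psm("WWWWK", protein_score = 60, hint = "t1"))
  ev <- map_psms(psms, isoforms)$evidence
  grp <- group_proteins(ev)
  expect_equal(max(grp$group_id), 1L)
  expect_equal(sum(grp$anchor), 1L)
  expect_equal(grp$isoform_id[grp$anchor], "iso1")

  disjoint <- map_psms(rbind(make_psm("AAAKW"), make_psm("CCCDE")),
                       iso_df(c("MAAAKWGG", "MCCCDEGG")))$evidence
  grp2 <- group_proteins(disjoint)
  expect_equal(max(grp2$group_id), 2L)
})

test_that("grouping matches hand-computed parsimony on a nested family", {
  # peptide sets: iso1 {A,N,C}, iso2 {A,N}, iso3 {A}, iso4 {D}, iso5 {C,D}
  seqs <- c("AAAAKNNNNKCCCCK", "AAAAKNNNNK", "AAAAKWWW", "DDDDKWWW",
            "CCCCKDDDDK")
  isoforms <- iso_df(seqs)
  psms <- do.call(rbind, lapply(c("AAAAK", "NNNNK", "CCCCK", "DDDDK"),
                                make_psm))
  ev <- map_psms(psms, isoforms)$evidence
  grp <- group_proteins(ev)
  g <- function(id) grp$group_id[grp$isoform_id == id]
  expect_equal(g("iso2"), g("iso1"))
  expect_equal(g("iso3"), g("iso1"))
  expect_false(g("iso4") == g("iso1"))
  expect_equal(g("iso4"), g("iso5"))
  expect_equal(max(grp$group_id), 2L)
})
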