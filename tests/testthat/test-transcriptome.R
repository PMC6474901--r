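# Six-frame translation, ORF extraction, component parsing, assembly stats.

test_that("FASTA reading parses Trinity-style components and normalizes sequences", {
  f <- write_fasta_tmp(c("comp35860_c0_seq1", "x", "plainid"),
                       c("ATGGCC", "atgn", "uuuAAA"))
  tr <- read_transcripts(f)
  expect_equal(tr$component_id, c("comp35860_c0", "x", "plainid"))
  expect_equal(tr$sequence[2], "ATGN")
  expect_equal(tr$sequence[3], "TTTAAA")
  expect_equal(tr$length_bp, nchar(tr$sequence))
})

test_that("ids without a component prefix become singleton components", {
  f <- write_fasta_tmp(c("a", "b", "c"), c("ATGATG", "CCCGGG", "TTTTTT"))
  tr <- read_transcripts(f)
  expect_equal(length(unique(tr$component_id)), 3L)
})

test_that("malformed and empty FASTA inputs error informatively", {
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ATGATG", ">x"), bad)
  expect_error(read_transcripts(bad), "line 1")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(read_transcripts(empty), "empty")
})

test_that("six-frame translation follows the standard code with N -> X", {
  fr <- six_frame_translate("ATGGCC")
  expect_equal(unname(fr["+1"]), "MA")
  # reverse complement of ATGGCC is GGCCAT: GGC -> G, CAT -> H (by hand)
  expect_equal(unname(fr["-1"]), "GH")
  expect_equal(names(fr), c("+1", "+2", "+3", "-1", "-2", "-3"))
  expect_equal(unname(six_frame_translate("ATGNAA")["+1"]), "MX")
  expect_error(six_frame_translate("AT"), "codon")
})

test_that("frame lengths and strand involution hold on random sequences", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(3:120, 1)
    dna <- random_dna(L)
    fr <- six_frame_translate(dna)
    expect_length(fr, 6L)
    for (off in 0:2) {
      expect_equal(nchar(fr[[paste0("+", off + 1)]]), (L - off) %/% 3)
      expect_equal(nchar(fr[[paste0("-", off + 1)]]), (L - off) %/% 3)
    }
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    fr2 <- six_frame_translate(rc)
    expect_equal(unname(fr2[c("-1", "-2", "-3")]), unname(fr[c("+1", "+2", "+3")]))
  }
})

test_that("ORF extraction splits on stops, honours min_aa and start/stop flags", {
  orfs <- extract_orfs(c("+1" = "MAAAK*GG"), min_aa = 3)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$aa_sequence, "MAAAK")
  expect_true(orfs$has_start)
  expect_true(orfs$has_stop)

  orfs <- extract_orfs(c("+1" = "AAAA"), min_aa = 3, mode = "keep_all")
  expect_false(orfs$has_start)
  expect_false(orfs$has_stop)

  expect_equal(nrow(extract_orfs(c("+1" = "AAAA"), min_aa = 3,
                                 mode = "require_start")), 0L)
})

test_that("ORF extraction matches a brute-force scan over random transcripts", {
  set.seed(12)
  for (rep in 1:15) {
    dna <- random_dna(60)
    frames <- six_frame_translate(dna)
    got <- extract_orfs(frames, min_aa = 4)
    want <- unlist(lapply(frames, oracle_orfs, min_aa = 4), use.names = FALSE)
    expect_setequal(got$aa_sequence, want)
  }
})

test_that("ORF extraction is invariant to stop padding at the sequence ends", {
  frames <- c("+1" = "MAAAKGGWWK")
  padded <- c("+1" = "**MAAAKGGWWK**")
  expect_equal(extract_orfs(frames, min_aa = 5)$aa_sequence,
               extract_orfs(padded, min_aa = 5)$aa_sequence)
})

test_that("assembly stats reproduce hand-enumerated N-statistics", {
  tr <- data.frame(length_bp = c(2, 2, 2, 10), component_id = "c")
  st <- assembly_stats(tr)
  expect_equal(st$N50_bp, 10)   # 10 >= 8 of 16 bases
  expect_equal(st$median_bp, 2)

  one <- assembly_stats(data.frame(length_bp = 100, component_id = "c"))
  expect_equal(one$N50_bp, 100)
  expect_equal(one$N30_bp, 100)
  expect_equal(one$median_bp, 100)

  expect_equal(assembly_stats(data.frame(length_bp = 1:9,
                                         component_id = "c"))$median_bp, 5)
  expect_error(assembly_stats(data.frame(length_bp = numeric())), "no transcripts")
})

test_that("variant labels follow decreasing mature mass with deterministic ties", {
  fam <- data.frame(mature_mass_kda = c(5.6, 6.6, 5.4, 6.5),
                    aa_sequence = c("CCC", "AAA", "DDD", "BBB"),
                    transcript_id = letters[1:4])
  lab <- assign_variant_names(fam)$variant_label
  expect_equal(lab, c("γ", "α", "δ", "β"))

  single <- assign_variant_names(data.frame(mature_mass_kda = 1,
                                            aa_sequence = "AAA",
                                            transcript_id = "t"))
  expect_equal(single$variant_label, "α")

  tie <- assign_variant_names(data.frame(mature_mass_kda = c(2, 2),
                                         aa_sequence = c("AAB", "AAA"),
                                         transcript_id = c("t1", "t2")))
  expect_equal(tie$variant_label, c("β", "α"))

  big <- data.frame(mature_mass_kda = 25:1, aa_sequence = replicate(25, random_aa(5)),
                    transcript_id = paste0("t", 1:25))
  expect_error(assign_variant_names(big), "exhausted")
})

test_that("variant labelling is a bijection consistent with the sort order", {
  set.seed(13)
  fam <- data.frame(mature_mass_kda = round(runif(8, 4, 22), 3),
                    aa_sequence = replicate(8, random_aa(12)),
                    transcript_id = paste0("t", 1:8))
  out <- assign_variant_names(fam)
  expect_setequal(out$variant_label, byssomap:::GREEK_LETTERS[1:8])
  ord_by_label <- order(match(out$variant_label, byssomap:::GREEK_LETTERS))
  ord_by_key <- order(-out$mature_mass_kda, out$aa_sequence, out$transcript_id)
  expect_equal(ord_by_label, ord_by_key)
})

test_that("signal completion extends a truncated variant from an intact donor", {
  donor <- "MKLALLAVIAFVAPSCYEATYPVPNQGRCLKDGQYFASGH"
  acceptor <- substring(donor, 12)      # lost most of the signal
  fam <- data.frame(aa_sequence = c(donor, acceptor),
                    has_start = c(TRUE, FALSE),
                    signal_pos = c(19L, NA_integer_))
  out <- complete_signal_from_variants(fam)
  expect_true(out$completed[2])
  expect_equal(out$aa_sequence[2], donor)   # prefix + acceptor remainder
  expect_equal(out$signal_pos[2], 19L)
  expect_equal(out$signal_source[2], "variant_completion")
})

test_that("signal completion refuses short or mismatched overlaps", {
  fam <- data.frame(aa_sequence = c("MKLALLAVIAFVAPSCYEATYPVPNQGR", "WWWWWWWWWWWW"),
                    has_start = c(TRUE, FALSE),
                    signal_pos = c(19L, NA_integer_))
  expect_warning(out <- complete_signal_from_variants(fam), "overlap")
  expect_false(out$completed[2])
  expect_equal(out$aa_sequence[2], "WWWWWWWWWWWW")
})
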