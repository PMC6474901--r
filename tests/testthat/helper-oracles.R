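# Independent brute-force oracles and tiny fixture builders. These are kept
# deliberately naive and separate from the implementation paths they check.

random_aa <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# enumerate tryptic peptides by scanning every (start, end) pair against the
# cleavage rule, independent of the implementation's fragment assembly
oracle_digest <- function(seq, missed = 0L, min_len = 1L, max_len = 1000L) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(res)
  is_cut <- function(i) i >= 1L && i < n && res[i] %in% c("K", "R") &&
    res[i + 1L] != "P"
  out <- list()
  for (s in 1:n) {
    if (s > 1L && !is_cut(s - 1L)) next
    for (e in s:n) {
      if (e < n && !is_cut(e)) next
      internal <- if (e > s) sum(vapply(s:(e - 1L), is_cut, logical(1))) else 0L
      if (internal > missed) next
      len <- e - s + 1L
      if (len < min_len || len > max_len) next
      out[[length(out) + 1L]] <- c(paste(res[s:e], collapse = ""), s)
    }
  }
  if (!length(out)) return(data.frame(peptide = character(), start = integer()))
  df <- data.frame(peptide = vapply(out, `[`, character(1), 1),
                   start = as.integer(vapply(out, `[`, character(1), 2)),
                   stringsAsFactors = FALSE)
  df[order(df$start, nchar(df$peptide)), , drop = FALSE]
}

# maximal non-stop segments of a frame string, via regex
oracle_orfs <- function(frame_string, min_aa) {
  m <- gregexpr("[^*]+", frame_string)[[1]]
  if (m[1] == -1L) return(character())
  segs <- regmatches(frame_string, gregexpr("[^*]+", frame_string))[[1]]
  segs[nchar(segs) >= min_aa]
}

# triple-loop tandem-repeat scan plus the same declarative nesting filter
oracle_repeats <- function(seq, min_unit = 2L, max_unit = 12L, min_copies = 2L) {
  n <- nchar(seq)
  max_unit <- min(max_unit, n %/% 2L)
  hits <- list()
  for (u in min_unit:max(min_unit, max_unit)) {
    for (s in 1:(n - 2L * u + 1L)) {
      unit <- substr(seq, s, s + u - 1L)
      k <- 1L
      while (s + (k + 1L) * u - 1L <= n &&
             substr(seq, s + k * u, s + (k + 1L) * u - 1L) == unit) k <- k + 1L
      left_max <- s - u < 1L || substr(seq, s - u, s - 1L) != unit
      if (k >= min_copies && left_max) {
        hits[[length(hits) + 1L]] <- data.frame(
          unit = unit, unit_len = u, copies = k, start = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(unit = character(), unit_len = integer(),
                      copies = integer(), start = integer()))
  }
  df <- unique(do.call(rbind, hits))
  end <- df$start + df$unit_len * df$copies - 1L
  drop <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || drop[j]) next
      contains <- df$start[j] <= df$start[i] && end[j] >= end[i]
      stronger <- df$copies[j] >= df$copies[i] &&
        df$unit_len[j] <= df$unit_len[i]
      strictly <- df$unit_len[j] < df$unit_len[i] ||
        (end[j] - df$start[j]) > (end[i] - df$start[i]) ||
        (df$unit_len[j] == df$unit_len[i] && df$start[j] < df$start[i])
      if (contains && stronger && strictly) { drop[i] <- TRUE; break }
    }
  }
  df <- df[!drop, , drop = FALSE]
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# naive overlapping substring count for fixed patterns
oracle_count_fixed <- function(seq, pattern) {
  n <- nchar(seq); p <- nchar(pattern); cnt <- 0L
  if (p > n) return(0L)
  for (i in 1:(n - p + 1L)) {
    if (substr(seq, i, i + p - 1L) == pattern) cnt <- cnt + 1L
  }
  cnt
}

write_fasta_tmp <- function(ids, seqs) {
  f <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", seqs), f)
  f
}
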