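# Exact tandem-repeat detection and degenerate-motif counting.

#' Find exact tandem repeats
#'
#' Scans every start position and unit length for maximal runs of at least
#' `min_copies` exact consecutive copies. A run is maximal when it cannot be
#' extended by a full unit on either side. Nested reports are suppressed: a
#' hit whose span lies within another hit's span, where the other hit has at
#' least as many copies and a unit no longer (and is not the identical hit),
#' is dropped -- e.g. `ABAB x2` inside an `AB x4` run, or the shifted `BA`
#' phase of the same run.
#'
#' @param aa_sequence protein sequence.
#' @param min_unit,max_unit unit length bounds (defaults 2 and 12).
#' @param min_copies minimum consecutive copies (default 2).
#' @return data.frame with `unit`, `unit_len`, `copies`, `start` (1-based),
#'   sorted by start then unit length.
#' @export
find_tandem_repeats <- function(aa_sequence, min_unit = 2L, max_unit = 12L,
                                min_copies = 2L) {
  residues <- strsplit(aa_sequence, "", fixed = TRUE)[[1]]
  n <- length(residues)
  if (max_unit > n / 2) max_unit <- floor(n / 2)
  hits <- list()
  for (u in seq(min_unit, max(min_unit, max_unit))) {
    if (2L * u > n) break
    i <- 1L
    while (i + 2L * u - 1L <= n) {
      unit <- substr(aa_sequence, i, i + u - 1L)
      # count consecutive copies
      k <- 1L
      while (i + (k + 1L) * u - 1L <= n &&
             substr(aa_sequence, i + k * u, i + (k + 1L) * u - 1L) == unit) {
        k <- k + 1L
      }
      if (k >= min_copies) {
        left_ok <- i - u < 1L ||
          substr(aa_sequence, i - u, i - 1L) != unit
        if (left_ok) {
          hits[[length(hits) + 1L]] <- list(unit = unit, unit_len = u,
                                            copies = k, start = i)
        }
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(unit = character(), unit_len = integer(),
                      copies = integer(), start = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    unit = vapply(hits, `[[`, character(1), "unit"),
    unit_len = vapply(hits, function(h) as.integer(h$unit_len), integer(1)),
    copies = vapply(hits, function(h) as.integer(h$copies), integer(1)),
    start = vapply(hits, function(h) as.integer(h$start), integer(1)),
    stringsAsFactors = FALSE
  )
  df <- suppress_nested_hits(df)
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

suppress_nested_hits <- function(df) {
  n <- nrow(df)
  if (n < 2L) return(df)
  end <- df$start + df$unit_len * df$copies - 1L
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      contains <- df$start[j] <= df$start[i] && end[j] >= end[i]
      stronger <- df$copies[j] >= df$copies[i] && df$unit_len[j] <= df$unit_len[i]
      strictly <- df$unit_len[j] < df$unit_len[i] ||
        (end[j] - df$start[j]) > (end[i] - df$start[i]) ||
        (df$unit_len[j] == df$unit_len[i] && df$start[j] < df$start[i])
      if (contains && stronger && strictly) {
        drop[i] <- TRUE
        break
      }
    }
  }
  df[!drop, , drop = FALSE]
}

#' Parse a degenerate motif pattern
#'
#' Accepts the field's notation for degenerate repeats: fixed residues,
#' alternation sets written `(Y/S)`, and `x` for "any amino acid", e.g.
#' `"YP(T/D)Y(P/T)EKK"` or `"YxxYxxxxY"`.
#'
#' @param text pattern string.
#' @return object of class `motif_pattern`: a list of character vectors, one
#'   per position.
#' @export
parse_pattern <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      j <- i + 1L
      set <- character()
      expecting <- "residue"
      repeat {
        if (j > length(chars)) {
          stop("unbalanced '(' opened at column ", i, call. = FALSE)
        }
        cj <- chars[j]
        if (expecting == "residue") {
          if (!cj %in% AA20) {
            stop("invalid residue '", cj, "' at column ", j, call. = FALSE)
          }
          set <- c(set, cj)
          expecting <- "sep"
        } else {
          if (cj == ")") break
          if (cj != "/") {
            stop("expected '/' or ')' at column ", j, call. = FALSE)
          }
          expecting <- "residue"
        }
        j <- j + 1L
      }
      if (!length(set)) stop("empty alternation at column ", i, call. = FALSE)
      positions[[length(positions) + 1L]] <- set
      i <- j + 1L
    } else if (ch == "x" || ch == "X") {
      positions[[length(positions) + 1L]] <- AA20
      i <- i + 1L
    } else if (ch %in% AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("invalid character '", ch, "' at column ", i, call. = FALSE)
    }
  }
  if (!length(positions)) stop("empty pattern", call. = FALSE)
  structure(positions, class = "motif_pattern", text = text)
}

#' @export
format.motif_pattern <- function(x, ...) {
  paste(vapply(unclass(x), function(set) {
    if (length(set) == 1L) set
    else if (length(set) == 20L) "x"
    else paste0("(", paste(set, collapse = "/"), ")")
  }, character(1)), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Count occurrences of a degenerate motif
#'
#' Counts every start position at which each sequence residue belongs to the
#' pattern's allowed set. Overlapping occurrences are counted by default
#' (required to reproduce published counts such as GNYG appearing five times
#' in Dbfp9-beta, where two occurrences share a glycine).
#'
#' @param aa_sequence protein sequence.
#' @param pattern a `motif_pattern` (or a string, parsed with
#'   [parse_pattern()]).
#' @param allow_overlap count overlapping occurrences (default TRUE).
#' @return list with `count` and `starts` (1-based positions).
#' @export
count_motif <- function(aa_sequence, pattern, allow_overlap = TRUE) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  residues <- strsplit(aa_sequence, "", fixed = TRUE)[[1]]
  plen <- length(pattern)
  if (plen > length(residues)) {
    return(list(count = 0L, starts = integer()))
  }
  starts <- integer()
  i <- 1L
  last_end <- 0L
  while (i <= length(residues) - plen + 1L) {
    ok <- TRUE
    for (k in seq_len(plen)) {
      if (!residues[i + k - 1L] %in% pattern[[k]]) {
        ok <- FALSE
        break
      }
    }
    if (ok && (allow_overlap || i > last_end)) {
      starts <- c(starts, i)
      last_end <- i + plen - 1L
    }
    i <- i + 1L
  }
  list(count = length(starts), starts = starts)
}

#' Derive a consensus pattern from aligned occurrences
#'
#' Position-wise union of equal-length occurrence strings: positions with a
#' single residue stay fixed, others become alternation sets ordered by
#' decreasing frequency. By construction the consensus matches every input
#' occurrence.
#'
#' @param occurrences character vector of >= 2 equal-length sequences.
#' @return a `motif_pattern`.
#' @export
consensus_from_occurrences <- function(occurrences) {
  if (length(occurrences) < 2L) stop("need at least 2 occurrences", call. = FALSE)
  lens <- nchar(occurrences)
  if (length(unique(lens)) != 1L) {
    stop("occurrences must have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(occurrences, "", fixed = TRUE))
  positions <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    tab <- table(col)
    # frequency order; ties resolved by first appearance down the column
    names(tab)[order(-as.numeric(tab), match(names(tab), unique(col)))]
  })
  structure(positions, class = "motif_pattern")
}
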