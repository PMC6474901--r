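# Packaged reference data: the published Dreissena bugensis foot protein
# (Dbfp) precursor sequences and their reported composition profiles.

#' Published Dbfp precursor sequences
#'
#' Returns the representative precursor sequence of each published quagga
#' mussel byssal protein family (Dbfp1 fragments and Dbfp2, Dbfp4-Dbfp17),
#' with curated signal-peptide cleavage positions. Underline markup carrying
#' the signal annotation does not survive plain-text transcription, so the
#' cleavage sites were curated to be consistent with the published mature
#' residue counts, molecular weights, isoelectric points and compositions;
#' each row's `note` records this. The two Dbfp1 entries are internal
#' fragments without signal peptides (`cleavage_pos = NA`).
#'
#' @return data.frame with columns `name`, `family`, `cleavage_pos`,
#'   `sequence`, `note`.
#' @examples
#' pre <- dbfp_precursors()
#' nchar(dbfp_mature("Dbfp9beta"))
#' @export
dbfp_precursors <- function() {
  path <- system.file("extdata", "dbfp_precursors.tsv", package = "byssomap",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$cleavage_pos <- suppressWarnings(as.integer(df$cleavage_pos))
  df
}

#' Mature sequence of a packaged Dbfp protein
#'
#' @param name a `name` from [dbfp_precursors()], e.g. `"Dbfp9beta"`.
#' @return the mature amino-acid string (signal peptide removed; fragments
#'   are returned whole).
#' @export
dbfp_mature <- function(name) {
  pre <- dbfp_precursors()
  i <- match(name, pre$name)
  if (is.na(i)) {
    stop("unknown protein '", name, "'; see dbfp_precursors()$name",
         call. = FALSE)
  }
  mature_sequence(pre$sequence[i], pre$cleavage_pos[i])
}

#' Reported composition profiles and categories of the Dbfp set
#'
#' The published prominent amino-acid mol% values and compositional category
#' of each of the 16 reported byssal proteins. The profiles are sparse
#' (residues below the reporting cutoff are absent). Dbfp1's profile comes
#' from earlier compositional analysis of the purified protein rather than a
#' translated sequence; Dbfp8's second-ranked residue is lysine, following
#' the running text (the tabulated one-letter code is a typographic slip).
#'
#' @return data.frame with `protein`, `molpct` (named-list column of sparse
#'   mol% vectors) and `category`.
#' @export
dbfp_reported_profiles <- function() {
  path <- system.file("extdata", "dbfp_reported_profiles.tsv",
                      package = "byssomap", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$molpct <- lapply(df$prominent_molpct, function(s) {
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(parts, `[[`, character(1), 1))
  })
  df$prominent_molpct <- NULL
  df
}
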