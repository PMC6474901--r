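# Physicochemical characterization of mature proteins: mass, charge, pI,
# composition, hydropathy, category, terminal-block pIs and a
# charge-hydropathy disorder proxy.

#' Mature sequence of a precursor
#'
#' Sequence properties of secreted proteins are computed after removal of the
#' predicted signal peptide. `cleavage_pos` is the 1-based position of the
#' last signal residue; the mature sequence starts at `cleavage_pos + 1`.
#' With no annotation the precursor is returned unchanged and flagged, so
#' downstream properties can be marked as computed on an immature sequence.
#'
#' @param aa_sequence precursor sequence.
#' @param cleavage_pos signal cleavage position, or `NA`.
#' @return the mature string, with attribute `immature_properties = TRUE`
#'   when no cleavage was applied.
#' @export
mature_sequence <- function(aa_sequence, cleavage_pos = NA_integer_) {
  if (is.na(cleavage_pos)) {
    return(structure(aa_sequence, immature_properties = TRUE))
  }
  if (cleavage_pos >= nchar(aa_sequence)) {
    stop("cleavage position ", cleavage_pos, " leaves no mature sequence (length ",
         nchar(aa_sequence), ")", call. = FALSE)
  }
  substring(aa_sequence, cleavage_pos + 1L)
}

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water, reported in kDa at full
#' internal precision. Monoisotopic masses are available by flag.
#'
#' @param aa_sequence protein sequence (standard 20 residues; `X` is an
#'   error, with offending positions listed).
#' @param monoisotopic use monoisotopic masses (default FALSE).
#' @return mass in kDa.
#' @export
average_mass <- function(aa_sequence, monoisotopic = FALSE) {
  residues <- aa_check(aa_sequence, allow_x = FALSE, what = "aa_sequence")
  tbl <- if (monoisotopic) AA_MONO_MASS else AA_AVERAGE_MASS
  w <- if (monoisotopic) MASS_WATER_MONO else MASS_WATER_AVERAGE
  (sum(tbl[residues]) + w) / 1000
}

#' Henderson-Hasselbalch net charge at a given pH
#'
#' `charge = sum over basic groups of 1 / (1 + 10^(pH - pKa))
#'         - sum over acidic groups of 1 / (1 + 10^(pKa - pH))`,
#' with the free N-terminus, K, R and H basic and the free C-terminus, D, E,
#' C and Y acidic. Cys and Tyr are included as ionizable following the
#' pepstats convention; both termini can be switched off for internal
#' segments.
#'
#' @param aa_sequence protein sequence.
#' @param pH pH value in (0, 14).
#' @param pka a [pka_set()].
#' @param include_cys_tyr treat C and Y as ionizable (default TRUE).
#' @param free_nterm,free_cterm include the terminal groups (default TRUE).
#' @return net charge in elementary charges.
#' @export
net_charge <- function(aa_sequence, pH = 7, pka = pka_set("emboss"),
                       include_cys_tyr = TRUE,
                       free_nterm = TRUE, free_cterm = TRUE) {
  stopifnot(pH > 0, pH < 14)
  residues <- aa_check(aa_sequence, allow_x = FALSE, what = "aa_sequence")
  cnt <- table(factor(residues, levels = AA20))
  basic <- function(pk) 1 / (1 + 10^(pH - pk))
  acidic <- function(pk) 1 / (1 + 10^(pk - pH))
  pos <- cnt[["K"]] * basic(pka$K) + cnt[["R"]] * basic(pka$R) +
    cnt[["H"]] * basic(pka$H) + if (free_nterm) basic(pka$nterm) else 0
  neg <- cnt[["D"]] * acidic(pka$D) + cnt[["E"]] * acidic(pka$E) +
    (if (free_cterm) acidic(pka$cterm) else 0) +
    if (include_cys_tyr) {
      cnt[["C"]] * acidic(pka$C) + cnt[["Y"]] * acidic(pka$Y)
    } else 0
  pos - neg
}

#' Isoelectric point by bisection
#'
#' The net charge is strictly decreasing in pH under the model, so the root
#' is unique; it is located by bisection on (0, 14) to `tol` pH units.
#' A sequence with no basic (resp. acidic) groups is pinned at the interval
#' edge.
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance in pH units (default 1e-3).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(aa_sequence, pka = pka_set("emboss"),
                              include_cys_tyr = TRUE,
                              free_nterm = TRUE, free_cterm = TRUE,
                              tol = 1e-3) {
  f <- function(p) net_charge(aa_sequence, p, pka, include_cys_tyr,
                              free_nterm, free_cterm)
  lo <- 1e-4; hi <- 14 - 1e-4
  if (f(lo) <= 0) return(lo)
  if (f(hi) >= 0) return(hi)
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Amino-acid composition in mole percent
#'
#' @param aa_sequence protein sequence.
#' @return named numeric vector over the 20 standard residues, summing
#'   to 100.
#' @export
composition_molpct <- function(aa_sequence) {
  residues <- aa_check(aa_sequence, allow_x = FALSE, what = "aa_sequence")
  cnt <- table(factor(residues, levels = AA20))
  stats::setNames(100 * as.numeric(cnt) / length(residues), AA20)
}

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding arithmetic mean of the Kyte-Doolittle scale over an odd window;
#' no edge padding, so the profile has `L - window + 1` values.
#'
#' @param aa_sequence protein sequence.
#' @param window odd window width, `<=` sequence length (default 9, the
#'   ProtScale default).
#' @return numeric vector of window means.
#' @export
hydropathy_profile <- function(aa_sequence, window = 9L) {
  residues <- aa_check(aa_sequence, allow_x = FALSE, what = "aa_sequence")
  n <- length(residues)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window > n) stop("window (", window, ") exceeds sequence length (",
                       n, ")", call. = FALSE)
  kd <- unname(KYTE_DOOLITTLE[residues])
  cs <- cumsum(c(0, kd))
  (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

#' Categorize a protein by amino-acid content
#'
#' Byssal proteins fall into three compositional categories; the decision
#' rule reproduces the published assignments: cysteine-rich iff C >= 10 mol%;
#' otherwise glycine/tyrosine-rich iff G >= 15 and Y >= 10; otherwise
#' proline-rich iff P >= 8.5 or P is the single most abundant residue;
#' otherwise uncategorized. Thresholds are engineering choices
#' reverse-engineered from the published category table.
#'
#' @param molpct named mol% vector (possibly sparse; absent residues count
#'   as 0).
#' @return one of `"C_rich"`, `"GY_rich"`, `"P_rich"`, `"uncategorized"`.
#' @export
categorize <- function(molpct) {
  get <- function(a) if (a %in% names(molpct)) molpct[[a]] else 0
  if (get("C") >= 10) return("C_rich")
  if (get("G") >= 15 && get("Y") >= 10) return("GY_rich")
  most <- names(molpct)[which.max(molpct)]
  if (get("P") >= 8.5 || (length(molpct) && identical(most, "P"))) {
    return("P_rich")
  }
  "uncategorized"
}

#' Isoelectric points of the terminal blocks
#'
#' Several byssal proteins segregate charge into N- and C-terminal blocks of
#' opposing pI. The first `n_len` and last `c_len` residues are scored as
#' free peptides (both termini ionizable).
#'
#' @param aa_sequence mature protein sequence.
#' @param n_len,c_len block lengths (default 15 each); their sum must not
#'   exceed the sequence length and neither may be zero.
#' @param pka a [pka_set()].
#' @return named numeric vector `c(nterm_pI, cterm_pI)`.
#' @export
segment_pI <- function(aa_sequence, n_len = 15L, c_len = 15L,
                       pka = pka_set("emboss")) {
  L <- nchar(aa_sequence)
  if (n_len < 1L || c_len < 1L) stop("zero-length segment", call. = FALSE)
  if (n_len + c_len > L) {
    stop("segments (", n_len, "+", c_len, ") exceed sequence length ", L,
         call. = FALSE)
  }
  c(nterm_pI = isoelectric_point(substr(aa_sequence, 1L, n_len), pka),
    cterm_pI = isoelectric_point(substring(aa_sequence, L - c_len + 1L), pka))
}

#' Charge-hydropathy disorder proxy
#'
#' Flags sequences on the disordered side of the classical charge-hydropathy
#' boundary: mean absolute net charge per residue at pH 7 greater than
#' `2.785 * <H> - 1.151`, where `<H>` is the mean Kyte-Doolittle hydropathy
#' normalized to 0-1. This is a coarse proxy reported as "disorder-prone"
#' only; it is not an energy-based disorder prediction.
#'
#' @param aa_sequence protein sequence, length >= 20 (else `NA`).
#' @param pka a [pka_set()].
#' @return logical flag, or `NA` for short sequences.
#' @export
charge_hydropathy_flag <- function(aa_sequence, pka = pka_set("emboss")) {
  residues <- aa_check(aa_sequence, allow_x = FALSE, what = "aa_sequence")
  if (length(residues) < 20L) return(NA)
  mean_charge <- abs(net_charge(aa_sequence, 7, pka)) / length(residues)
  h_norm <- mean((unname(KYTE_DOOLITTLE[residues]) + 4.5) / 9)
  mean_charge > 2.785 * h_norm - 1.151
}

#' Full physicochemical profile of a mature protein
#'
#' @param aa_sequence mature protein sequence.
#' @param pka a [pka_set()].
#' @param window hydropathy window (odd; default 9).
#' @param n_len,c_len terminal block lengths for [segment_pI()].
#' @return list of class `property_profile` with `mature_len`,
#'   `avg_mass_kda`, `pI`, `charge_at_pH7`, `molpct`, `hydropathy`,
#'   `category`, `nterm_segment_pI`, `cterm_segment_pI`, `disorder_prone`.
#' @export
property_profile <- function(aa_sequence, pka = pka_set("emboss"),
                             window = 9L, n_len = 15L, c_len = 15L) {
  L <- nchar(aa_sequence)
  molpct <- composition_molpct(aa_sequence)
  seg <- if (n_len + c_len <= L) segment_pI(aa_sequence, n_len, c_len, pka)
         else c(nterm_pI = NA_real_, cterm_pI = NA_real_)
  structure(list(
    mature_len = L,
    avg_mass_kda = average_mass(aa_sequence),
    pI = isoelectric_point(aa_sequence, pka),
    charge_at_pH7 = net_charge(aa_sequence, 7, pka),
    molpct = molpct,
    hydropathy = if (window <= L) hydropathy_profile(aa_sequence, window) else numeric(),
    category = categorize(molpct),
    nterm_segment_pI = unname(seg["nterm_pI"]),
    cterm_segment_pI = unname(seg["cterm_pI"]),
    disorder_prone = charge_hydropathy_flag(aa_sequence, pka)
  ), class = "property_profile")
}
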