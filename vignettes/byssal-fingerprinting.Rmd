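---
title: "Fingerprinting byssal proteins from a foot transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting byssal proteins from a foot transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(byssomap)
```

## The problem

Freshwater mussels (the quagga mussel *Dreissena bugensis* and its relatives)
attach underwater through the byssus, a bundle of protein threads ending in
adhesive plaques. Most of the proteins that make up this adhesive are small,
secreted, highly repetitive, and absent from sequence databases, so they
cannot be identified by a conventional database search. The workaround is
proteotranscriptomic fingerprinting: assemble a transcriptome from the foot
(the secretory organ), translate every transcript in all six reading frames,
and match LC-MS/MS peptide spectra from freshly induced byssal secretions
against that translated library. Candidate byssal proteins are then selected
by score thresholds, cleaned of cellular contaminants by homology, restricted
to proteins carrying a signal peptide (the hallmark of secretion), and
characterized: mass, isoelectric point, charge, amino-acid composition,
hydropathy, tandem repeats and motifs.

`byssomap` implements that pipeline as tested, reusable functions, together
with a seeded synthetic-data generator so that every stage can be exercised
end to end without the original raw data.

## Pipeline stages and their models

### Six-frame translation and ORFs

`six_frame_translate()` translates the forward strand and the reverse
complement at offsets 0–2 under the standard genetic code (no organellar
context applies); stop codons become `*` and any codon containing `N`
becomes `X`, which never matches a peptide. `extract_orfs()` splits each
frame on stops. The default policy keeps segments that do not begin with
methionine (`mode = "keep_all"`), because assembled transcripts are often
5'-truncated and several reported byssal proteins genuinely lack observed
start codons; `require_start` is available by flag. The default minimum ORF
length is 30 residues: the smallest reported mature byssal protein is about
40 residues, and the margin admits fragments without flooding the isoform
table with spurious micro-ORFs.

Transcript identifiers of the form `comp<N>_c<K>_seq<J>` are grouped into
components — gene-like clusters produced by de novo assemblers — and the
variants within a component are labelled with Greek letters in decreasing
mature-mass order (`assign_variant_names()`), with lexicographic tie-breaks
so labelling is deterministic.

### Peptide evidence

Matching is sequence-level: the upstream search engine has already scored
spectra, and its parent/fragment mass tolerances are carried only as
metadata. `digest()` implements tryptic specificity (cleave after K/R, not
before P, up to two missed cleavages). PSM peptides may carry lower-case
marks for deamidated N/Q and hydroxylated Y (DOPA); marks never change which
template residue matches (`expand_modification_keys()`). Isoleucine and
leucine are treated as indistinguishable by default, since their residue
masses are identical in MS. Peptides may match anywhere in an isoform —
gel-band digests show ragged, non-tryptic termini — but non-tryptic matches
are flagged. Coverage is computed on the mature sequence, after signal
removal, matching the convention used for the published coverage figures.
When no protein-level score is supplied with the PSM table, the fallback is
the sum of the top three peptide scores; this is a documented stand-in, not
a reconstruction of the upstream engine's score.

### Candidate selection

The acceptance thresholds are the study's: peptide −10lgP ≥ 15, protein
−10lgP ≥ 50, ALC ≥ 80% for purely de-novo peptides, and at least two
qualifying spectra. De-novo-only spectra never count toward the spectrum
minimum by default (they are tabulated separately upstream); a flag changes
this. An overrides list reproduces the study's manually justified
inclusions (a protein scored 48 was accepted on external evidence); every
override is flagged in the output.

Contaminant removal rejects a protein only when its best hit against a
*contaminant* database has expect value strictly below 1e−6 — "below e−6"
read literally. A separate allowlist class exists because strong homology to
byssal proteins of related species is expected and must never reject; the
membership of both lists is user-supplied.

The signal-peptide gate takes annotations in priority order: an external
annotation file always wins; next, truncated variants are completed from an
intact variant of the same component when their N-terminus reproduces the
donor's signal region exactly over at least 10 residues (the completion
window extends 10 residues into the mature sequence, since variants may
diverge further downstream); finally a built-in heuristic applies the
classical n/h/c-region rule — non-negative charge in the first five
residues, a ≥6-residue hydrophobic core with mean Kyte–Doolittle ≥ 1.6
within positions 3–20, small residues at −3/−1, and a preference for sites
about five residues past the core (a typical c-region length). On the
packaged reference set this heuristic places 11 of 15 curated cleavage
sites within ±3 residues; the misses have unusually long signals or polar
c-regions, which is why annotation files take priority.

### Characterization

Physicochemical properties are computed on the mature sequence. Masses are
average (isotope-weighted) residue masses plus one water, matching
"theoretical mass" conventions; monoisotopic masses are available by flag.
Charge follows the Henderson–Hasselbalch sum over ionizable groups, and the
isoelectric point is found by bisection (default resolution 1e−3 pH units;
the charge is strictly decreasing in pH, so the root is unique). The
default pKa set is the EMBOSS pepstats set, because the published pI values
are only reproducible under a pepstats-like model; Bjellqvist and Lehninger
sets are selectable, and Cys/Tyr ionizability can be toggled — net charges
near neutral pH are sensitive to it.

The compositional category rule (`categorize()`) is deliberately
reverse-engineered to reproduce the published table exactly: C-rich iff
C ≥ 10 mol%; else G/Y-rich iff G ≥ 15 and Y ≥ 10; else P-rich iff P ≥ 8.5
or proline is the single most abundant residue; else uncategorized. These
thresholds are engineering choices documented as such, not biological
constants. Terminal-block pIs (default 15 residues each end, scored as free
peptides) quantify the acidic-N/basic-C block structure seen in several
byssal proteins. The disorder flag is the classical charge–hydropathy
boundary (mean net charge per residue vs. 2.785·⟨H⟩ − 1.151); it is a
coarse proxy reported as "disorder-prone" only, not an energy-based
disorder prediction.

### Repeats and motifs

Tandem repeats are exact: the published repeats are exact, and degenerate
variation is handled at the motif layer instead. The scanner reports
maximal runs of ≥2 copies for unit lengths 2–12 and suppresses nested
reports (a run wholly explained by a shorter unit with more copies over the
same span, or a shifted phase of the same run). Motif counting accepts the
field's notation — `(Y/S)GYPGN`, `YxxYxxxxY` with `x` as any residue — and
counts overlapping occurrences by default; the published count of five
`GNYG` occurrences requires overlap counting, which fixed the default.

## The synthetic-data generator

`simulate_dataset()` emulates the study's inputs with planted ground truth:
secreted families with signal peptides constructed to satisfy the n/h/c
heuristic, Greek-letter variants made by seeded internal deletions and
substitutions, planted tandem repeats from the published repeat units,
mature masses in 4–22 kDa (the reported range), cellular contaminants
without signal peptides but with strong contaminant-database hits, and four
samples: a whole thread/plaque extract plus ~6, ~7 and ~14 kDa gel bands
that only contain proteins whose mature mass falls in the band window.
Peptide scores for true PSMs are Normal(35, 8) truncated at zero with at
least two spectra per protein guaranteed above score 20; decoy noise is
residue-shuffled (re-shuffled on collision), flagged de-novo-only, with
scores Normal(10, 5). Contaminants receive *passing* protein scores so that
only the homology filter can remove them — the property under test.

What the generator does not emulate: real spectra (no m/z peaks, no
retention times), sequencing or assembly error inside coding regions,
shared peptides across unrelated families, and expression-level effects.
Passing the recovery tests therefore shows the pipeline's logic is correct
under the stated score model, not that the thresholds are optimal for real
instruments.

Default test sizes are 4 families × 2 variants plus 3 contaminants and 15
decoys, with recovery checked over 10 seeds — small enough to run the whole
suite in a few minutes on one CPU while still exercising every stage,
including a 5'-truncated variant whose signal must be completed from its
intact sibling.

## Reference data and curation

`dbfp_precursors()` ships the published representative sequences of the
sixteen reported byssal protein families (Dbfp1 fragments, Dbfp2,
Dbfp4–Dbfp17). Two curation notes matter. First, the signal-peptide
underlining of the original table does not survive plain-text
transcription, so cleavage sites were curated to be consistent with the
published mature lengths, masses, pIs and compositions; each row carries a
note. Second, a handful of printed numbers are internally inconsistent
(e.g. a printed residue count that disagrees with the printed mol% of the
same protein); where that happens the curation follows the composition,
which is the quantity the acceptance checks anchor on.

Two published values are not reproducible from the printed sequences under
any standard pKa set, and the package reports its computed values rather
than the printed ones: the Dbfp9 N-terminal block pI (printed 3.4; the
model gives 3.66 — the printed value would require five aspartates where
the printed segment has four) and the mature Dbfp5 net charge at pH 7
(printed +4.2; the model gives +4.79, while the *pI* of the very same
sequence reproduces the printed 8.7, so the sequence and charge model are
sound). The corresponding assertions are kept at their stated tolerances
and fail honestly.

## Worked example

```{r example, eval = FALSE}
library(byssomap)

m9 <- dbfp_mature("Dbfp9beta")
profile <- property_profile(m9)
round(profile$avg_mass_kda, 1)    # 7.9
round(profile$pI, 1)              # 4.6
profile$category                  # "GY_rich"
count_motif(m9, "GNYG")$count     # 5

ds <- simulate_dataset(synthetic_config(), seed = 1)
res <- run_pipeline(ds$transcripts, ds$psms,
                    hits = ds$hits, signals = ds$signals)
subset(res$report, status == "accepted",
       select = c(name, representative, mw_kda, pI, category))
```

## Known limitations

* Signal-peptide prediction is a classical heuristic, not a trained model;
  on real precursors an external predictor's annotation file should be
  supplied and will take priority.
* Protein grouping is greedy subset-merging, adequate for nested variant
  families but not a full parsimony solver for arbitrarily entangled
  shared-peptide graphs.
* Spectral counts are a coarse abundance proxy; no FDR estimation is
  performed — score thresholds are taken as given, as in the original
  analysis.
* The repeat scanner is exact by design and will not find degenerate
  repeats directly; express those as motif patterns.
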