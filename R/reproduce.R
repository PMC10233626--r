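# Driver for re-deriving the published reverse-gyrase comparisons from
# locally provided coordinate and sequence files. The package ships no
# crystal structures; point `dir` at a folder of files fetched from the
# PDB / AlphaFold / UniProt to run the full comparison set.

#' Re-derive the reverse-gyrase latch comparisons from local files
#'
#' Expects (any subset of) `7fse.pdb`/`.cif` (minimal latch),
#' `7fsf.pdb` (Y851F), `4ddu.pdb`, `4ddt.pdb` (wild type), `3oiy.pdb`,
#' `3p4x.pdb` (helicase domain) and `B7IEV8.fasta` under `dir`. For every
#' pair present it runs the latch-excluded superposition with outlier
#' rejection, the Tyr364 hydroxyl displacement probe, the minimal-latch
#' motif classification and contact inventory, and the pairwise
#' identity/similarity of the two minimal-latch enzymes. Pairs whose
#' inputs are missing are reported as skipped, not errors; every
#' superposition row carries its full atom pairing for audit.
#'
#' @param dir Directory with the downloaded files.
#' @param out_dir Optional report directory (TSV/JSON).
#' @param config A `latchkit_config`; defaults to the packaged
#'   *T. maritima* domain map.
#' @return List with `rmsd`, `motifs`, `contacts`, `probes`, `alignment`
#'   tibbles (entries `NULL` when inputs are absent).
#' @export
reproduce_latch_study <- function(dir, out_dir = NULL, config = NULL) {
  cfg <- config %||% load_config(tmaritima_config())
  find_file <- function(stem) {
    hits <- list.files(dir, pattern = paste0("^", stem, "\\.(pdb|ent|cif)$"),
                       ignore.case = TRUE, full.names = TRUE)
    if (length(hits) > 0) hits[1] else NULL
  }
  have <- purrr::compact(list(
    rgyr_minlatch = find_file("7fse"),
    rgyr_y851f = find_file("7fsf"),
    wt_4ddu = find_file("4ddu"),
    wt_4ddt = find_file("4ddt")
  ))
  out <- list(rmsd = NULL, motifs = NULL, contacts = NULL, probes = NULL,
              alignment = NULL, skipped = character())
  if (length(have) >= 2) {
    # superpose all residues except the latch regions (full latch in the
    # comparators, minimal latch in 7fse share author numbering 1-386 /
    # 460-1104)
    fit_spans <- cfg$regions$all_minus_latch_full %||% "A:1-388,A:460-1104"
    out$rmsd <- run_structure_compare(unlist(have), fit_spans = fit_spans,
                                      config = cfg, out_dir = out_dir)$rmsd
    probes <- tibble(chain = "A", resno = 364, elety = "OH")
    out$probes <- tryCatch(
      run_structure_compare(unlist(have), fit_spans = cfg$regions$h2_minus_latch,
                            probes = probes, config = cfg)$probes,
      error = function(e) NULL)
  } else {
    out$skipped <- c(out$skipped,
                     "superpositions: need at least two of 7fse/7fsf/4ddu/4ddt")
  }
  if (!is.null(have$rgyr_minlatch)) {
    st <- read_structure(have$rgyr_minlatch)
    hb <- backbone_hbonds(st, cfg$hbond_cutoff)
    out$motifs <- classify_hairpins(st, hb, relaxed = cfg$relaxed)
    out$contacts <- region_contacts(st, cfg$regions$latch_minimal,
                                    cfg$regions$topoisomerase,
                                    cutoff = cfg$contact_cutoff)
  } else {
    out$skipped <- c(out$skipped, "motifs/contacts: 7fse not found")
  }
  fa <- list.files(dir, pattern = "B7IEV8.*\\.(fa|fasta)$", full.names = TRUE,
                   ignore.case = TRUE)
  if (length(fa) > 0 && !is.null(have$rgyr_minlatch)) {
    taf <- read_sequences(fa[1])$sequence[1]
    tma <- chain_sequence(read_structure(have$rgyr_minlatch))
    out$alignment <- smith_waterman(taf, tma, matrix = cfg$matrix,
                                    gap_open = cfg$gap_open,
                                    gap_extend = cfg$gap_extend)
  } else {
    out$skipped <- c(out$skipped, "alignment: B7IEV8 fasta and/or 7fse missing")
  }
  if (!is.null(out_dir)) {
    for (nm in c("motifs", "contacts", "probes", "alignment")) {
      if (!is.null(out[[nm]])) write_report(out[[nm]], out_dir, nm)
    }
  }
  out
}
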