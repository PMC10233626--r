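# Desk-scale orchestration: motif scan, structure comparison and latch
# survey, each driven by a declarative config and writing TSV + JSON
# reports into a run directory.

#' Load a pipeline configuration
#'
#' Configs are YAML; values not given fall back to package defaults
#' (H-bond cutoff -0.5 kcal/mol, contact cutoff 4.5 A, CA superposition
#' with 2.0 A rejection over 5 cycles, BLOSUM62 with gap 10/0.5). The
#' packaged `tmaritima_domains.yaml` carries the *T. maritima* reverse
#' gyrase domain map used for named selections.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @param overrides Named list merged over the file values.
#' @return A list of class `latchkit_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    hbond_cutoff = -0.5,
    contact_cutoff = 4.5,
    atom_mode = "CA",
    reject_cutoff = 2.0,
    max_cycles = 5,
    relaxed = TRUE,
    matrix = "BLOSUM62",
    gap_open = 10,
    gap_extend = 0.5,
    gap_threshold = 6,
    regions = list()
  )
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- utils::modifyList(utils::modifyList(defaults, vals), overrides)
  class(cfg) <- "latchkit_config"
  cfg
}

#' Packaged T. maritima reverse gyrase domain map
#'
#' @return Path to the YAML config shipped with the package.
#' @export
tmaritima_config <- function() {
  system.file("extdata", "tmaritima_domains.yaml", package = "latchkit",
              mustWork = TRUE)
}

write_report <- function(tbl, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")))
  jsonlite::write_json(tbl, file.path(out_dir, paste0(name, ".json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' Scan structures for hairpin motifs and classify their loops
#'
#' @param paths Character vector of structure files (PDB/mmCIF).
#' @param config A `latchkit_config` (or `NULL` for defaults).
#' @param out_dir Optional report directory (writes `motifs.tsv/.json`).
#' @return Tibble with one row per motif across all inputs, carrying the
#'   source file as provenance.
#' @export
run_motif_scan <- function(paths, config = NULL, out_dir = NULL) {
  cfg <- config %||% load_config()
  rows <- purrr::map(paths, function(p) {
    st <- read_structure(p)
    hb <- backbone_hbonds(st, energy_cutoff = cfg$hbond_cutoff)
    res <- classify_hairpins(st, hb, relaxed = cfg$relaxed)
    if (nrow(res) > 0) {
      res$structure_id <- structure_id(st)
      res$source <- p
    }
    res
  })
  out <- bind_rows(rows)
  write_report(out, out_dir, "motifs")
  out
}

#' Pairwise structure comparison: r.m.s.d. matrix, probes, contacts
#'
#' Superposes every structure pair over the fit selection with outlier
#' rejection, reports per-pair r.m.s.d.s, optional probe displacements in
#' the fitted frame and optional contact inventories per structure.
#'
#' @param paths Character vector of >= 2 structure files.
#' @param fit_spans Span string for the fit region (`NULL` = all shared
#'   residues).
#' @param probes Optional probe table (see [probe_displacement()]).
#' @param contact_regions Optional list `list(a = span, b = span)` to
#'   inventory contacts within each structure.
#' @param config A `latchkit_config` (or `NULL`).
#' @param out_dir Optional report directory.
#' @return List with `rmsd` (pairwise tibble), `probes`, `contacts`.
#' @export
run_structure_compare <- function(paths, fit_spans = NULL, probes = NULL,
                                  contact_regions = NULL, config = NULL,
                                  out_dir = NULL) {
  cfg <- config %||% load_config()
  if (length(paths) < 2 && is.null(contact_regions)) {
    abort("need at least two structures to compare")
  }
  sts <- purrr::map(paths, read_structure)
  ids <- purrr::map_chr(sts, structure_id)
  pairs <- utils::combn(seq_along(sts), 2)
  rmsd_rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- tryCatch({
      pr <- pair_atoms(sts[[i]], sts[[j]], fit_spans, cfg$atom_mode)
      fit <- refine_superpose(pr, cfg$reject_cutoff, cfg$max_cycles)
      tibble(ref = ids[i], mov = ids[j], rmsd = fit$rmsd,
             n_atoms_used = fit$n_atoms_used, n_rejected = fit$n_rejected,
             error = NA_character_)
    }, error = function(e) {
      tibble(ref = ids[i], mov = ids[j], rmsd = NA_real_,
             n_atoms_used = NA_integer_, n_rejected = NA_integer_,
             error = conditionMessage(e))
    })
    res
  }) |> bind_rows()
  probe_rows <- NULL
  if (!is.null(probes)) {
    probe_rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      pd <- probe_displacement(sts[[i]], sts[[j]], fit_spans, probes,
                               atom_mode = cfg$atom_mode,
                               reject_cutoff = cfg$reject_cutoff,
                               max_cycles = cfg$max_cycles)
      pd$ref <- ids[i]; pd$mov <- ids[j]
      pd
    }) |> bind_rows()
  }
  contact_rows <- NULL
  if (!is.null(contact_regions)) {
    contact_rows <- purrr::map(seq_along(sts), function(i) {
      ct <- region_contacts(sts[[i]], contact_regions$a, contact_regions$b,
                            cutoff = cfg$contact_cutoff)
      if (nrow(ct) > 0) ct$structure_id <- ids[i]
      ct
    }) |> bind_rows()
  }
  if (!is.null(out_dir)) {
    write_report(rmsd_rows, out_dir, "rmsd")
    if (!is.null(probe_rows)) write_report(probe_rows, out_dir, "probes")
    if (!is.null(contact_rows)) write_report(contact_rows, out_dir, "contacts")
  }
  list(rmsd = rmsd_rows, probes = probe_rows, contacts = contact_rows)
}

#' Latch survey: region table, length clusters and charge summary
#'
#' Maps the reference latch span through a multiple alignment, computes
#' per-region length/charge/hydrophobicity, clusters the lengths and
#' partitions the charges by sign.
#'
#' @param msa Alignment tibble (from [read_sequences()]) or file path.
#' @param reference_id,ref_start,ref_end Reference anchors, as in
#'   [map_alignment_region()].
#' @param config A `latchkit_config` (or `NULL`).
#' @param out_dir Optional report directory.
#' @return List with `regions` (per-sequence table), `clusters`,
#'   `counts` (charge-sign tibble) and `length_histogram` (bin width 5).
#' @export
run_latch_survey <- function(msa, reference_id, ref_start, ref_end,
                             config = NULL, out_dir = NULL) {
  cfg <- config %||% load_config()
  if (is.character(msa) && length(msa) == 1) msa <- read_sequences(msa)
  regions <- map_alignment_region(msa, reference_id, ref_start, ref_end)
  cs <- charge_summary(regions)
  clusters <- cluster_lengths(regions$length[regions$length > 0],
                              gap_threshold = cfg$gap_threshold)
  hist_tbl <- regions |>
    filter(.data$length > 0) |>
    mutate(bin = 5 * (.data$length %/% 5)) |>
    dplyr::count(.data$bin, name = "count") |>
    mutate(bin_label = paste0(.data$bin, "-", .data$bin + 4))
  if (!is.null(out_dir)) {
    write_report(cs$table, out_dir, "latch_regions")
    write_report(clusters, out_dir, "length_clusters")
    write_report(cs$counts, out_dir, "charge_counts")
    write_report(hist_tbl, out_dir, "length_histogram")
  }
  list(regions = cs$table, clusters = clusters, counts = cs$counts,
       length_histogram = hist_tbl)
}
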