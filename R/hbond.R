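# Backbone hydrogen bonds, Kabsch-Sander style.
#
# Crystal structures rarely carry hydrogens, so amide H positions are
# inferred first; bond energies then follow the classic electrostatic
# model with partial charges on N-H and C=O.

KS_Q1Q2F <- 0.084 * 332   # kcal/mol * Angstrom
KS_NO_PREFILTER <- 5.2    # candidate N..O distance ceiling, Angstrom

#' Infer backbone amide hydrogen positions
#'
#' Places the amide hydrogen of each residue `i > 1` at 1 A from N along
#' the direction of the preceding carbonyl, i.e. `H = N + unit(C(i-1) -
#' O(i-1))` (the Kabsch-Sander convention). Prolines and chain-start
#' residues receive no hydrogen; residues whose preceding carbonyl is
#' missing are skipped with a warning.
#'
#' @param structure A `struct_tbl` with backbone atoms.
#' @return The structure with added `"H"` atom rows.
#' @export
infer_amide_hydrogens <- function(structure) {
  structure <- structure[structure$elety != "H", , drop = FALSE]
  new_rows <- list()
  skipped <- 0L
  for (ch in unique(structure$chain)) {
    bb <- backbone_matrices(structure, ch)
    rt <- bb$residues
    n <- nrow(rt)
    if (n < 2) next
    for (k in 2:n) {
      if (rt$resname[k] == "PRO") next
      if (any(is.na(bb$N[k, ]))) next
      if (any(is.na(bb$C[k - 1, ])) || any(is.na(bb$O[k - 1, ]))) {
        skipped <- skipped + 1L
        next
      }
      h <- bb$N[k, ] + unit3(bb$C[k - 1, ] - bb$O[k - 1, ])
      new_rows[[length(new_rows) + 1L]] <- tibble(
        chain = ch, resno = rt$resno[k], insert = rt$insert[k],
        resname = rt$resname[k], elety = "H", element = "H",
        x = h[1], y = h[2], z = h[3], occupancy = 1
      )
    }
  }
  if (skipped > 0) {
    warn(paste0(skipped, " residue(s) skipped: preceding carbonyl missing"))
  }
  out <- bind_rows(structure, bind_rows(new_rows)) |>
    arrange(.data$chain, .data$resno, .data$insert)
  new_structure_tbl(out, id = structure_id(structure),
                    source_format = attr(structure, "source_format") %||% "r")
}

#' Detect backbone hydrogen bonds (Kabsch-Sander energy model)
#'
#' For every donor (backbone N-H) / acceptor (backbone C=O) pair with N..O
#' distance at most 5.2 A and sequence separation of at least two
#' residues, the electrostatic energy
#' \deqn{E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' (kcal/mol) is evaluated; pairs with `E < energy_cutoff` are reported.
#' Both donor-to-acceptor directions are scanned.
#'
#' @param structure A `struct_tbl`; amide hydrogens are inferred
#'   automatically if absent.
#' @param energy_cutoff Acceptance threshold in kcal/mol; must be
#'   negative (default -0.5).
#' @return Tibble with one row per bond: donor/acceptor chain, residue
#'   number and insertion code, `energy` (kcal/mol) and `dist_no` (N..O, A).
#' @export
backbone_hbonds <- function(structure, energy_cutoff = -0.5) {
  if (energy_cutoff >= 0) abort("`energy_cutoff` must be negative (kcal/mol)")
  if (!"H" %in% structure$elety) structure <- infer_amide_hydrogens(structure)
  per_chain <- purrr::map(unique(structure$chain), function(ch) {
    bb <- backbone_matrices(structure, ch)
    list(chain = ch, bb = bb)
  })
  rows <- list()
  for (don_set in per_chain) {
    for (acc_set in per_chain) {
      bbd <- don_set$bb; bba <- acc_set$bb
      ok_d <- which(!is.na(bbd$H[, 1]) & !is.na(bbd$N[, 1]))
      ok_a <- which(!is.na(bba$C[, 1]) & !is.na(bba$O[, 1]))
      if (length(ok_d) == 0 || length(ok_a) == 0) next
      # pairwise N..O distances, prefiltered
      dON <- outer_dist(bbd$N[ok_d, , drop = FALSE], bba$O[ok_a, , drop = FALSE])
      cand <- which(dON <= KS_NO_PREFILTER, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      for (r in seq_len(nrow(cand))) {
        i <- ok_d[cand[r, 1]]; j <- ok_a[cand[r, 2]]
        same_chain <- don_set$chain == acc_set$chain
        if (same_chain && abs(i - j) < 2) next
        e <- KS_Q1Q2F * (1 / dON[cand[r, 1], cand[r, 2]] +
                           1 / vnorm(bba$C[j, ] - bbd$H[i, ]) -
                           1 / vnorm(bba$O[j, ] - bbd$H[i, ]) -
                           1 / vnorm(bba$C[j, ] - bbd$N[i, ]))
        if (e < energy_cutoff) {
          rows[[length(rows) + 1L]] <- tibble(
            donor_chain = don_set$chain,
            donor_resno = bbd$residues$resno[i],
            donor_insert = bbd$residues$insert[i],
            acceptor_chain = acc_set$chain,
            acceptor_resno = bba$residues$resno[j],
            acceptor_insert = bba$residues$insert[j],
            energy = e,
            dist_no = dON[cand[r, 1], cand[r, 2]]
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(donor_chain = character(), donor_resno = integer(),
                  donor_insert = character(), acceptor_chain = character(),
                  acceptor_resno = integer(), acceptor_insert = character(),
                  energy = double(), dist_no = double()))
  }
  bind_rows(rows) |> arrange(.data$donor_chain, .data$donor_resno,
                             .data$acceptor_chain, .data$acceptor_resno)
}

# all-pairs Euclidean distances between rows of two n x 3 matrices
outer_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
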