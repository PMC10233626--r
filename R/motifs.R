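# Beta-hairpin detection and classification of the capping loop as a
# beta-turn or a type-1/type-2 beta-bulge loop.
#
# Taxonomy (Milner-White / Sibanda): the loop capping a two-stranded
# antiparallel beta-sheet has 4 residues in a beta-turn, 5 in a type-1
# bulge loop and 6 in a type-2 bulge loop. Residue i is the first residue
# of the loop span; type 1 is flagged by the hydrogen bond
# N-H(i) -> C=O(i+4), type 2 by N-H(i) -> C=O(i+5). Both types share a
# second characteristic bond C=O(i) -> N-H(i+4), which real structures
# often lack -- hence the relaxed (default) mode that requires only the
# first bond and records the evidence for the second.

has_hbond <- function(hbonds, chain, don, acc) {
  any(hbonds$donor_chain == chain & hbonds$acceptor_chain == chain &
        hbonds$donor_resno == don & hbonds$acceptor_resno == acc)
}

# least-squares axis direction through a set of CA positions
strand_axis <- function(ca) {
  c0 <- colMeans(ca)
  sv <- svd(sweep(ca, 2, c0))
  v <- sv$v[, 1]
  # orient along the chain
  if (sum((ca[nrow(ca), ] - ca[1, ]) * v) < 0) v <- -v
  v
}

#' Find two-stranded antiparallel beta-hairpins
#'
#' Builds Kabsch-Sander antiparallel bridges from backbone hydrogen bonds
#' (residues `i`, `j` bridge if both `HB(i -> j)` and `HB(j -> i)` exist,
#' or both `HB(i-1 -> j+1)` and `HB(j-1 -> i+1)`), merges consecutive
#' bridges into ladders, and reports every ladder whose two strands lie on
#' the same chain and are joined by a loop of at most `max_loop` residues.
#'
#' @param structure A `struct_tbl`.
#' @param hbonds Output of [backbone_hbonds()]; computed if `NULL`.
#' @param max_loop Longest loop (residues between the strands) still
#'   reported as a hairpin (default 8).
#' @return Tibble, one row per motif: chain, strand spans, loop span,
#'   `loop_length`, `orientation` and the inter-strand `twist_angle`
#'   (degrees, angle between least-squares strand axes).
#' @export
find_beta_hairpins <- function(structure, hbonds = NULL, max_loop = 8) {
  if (is.null(hbonds)) hbonds <- backbone_hbonds(structure)
  out <- list()
  for (ch in unique(structure$chain)) {
    bb <- backbone_matrices(structure, ch)
    rt <- bb$residues
    n <- nrow(rt)
    if (n < 6) next
    hb_ch <- hbonds[hbonds$donor_chain == ch & hbonds$acceptor_chain == ch, ]
    # positional indices (author numbering order) of bonds
    di <- match(paste(hb_ch$donor_resno, hb_ch$donor_insert),
                paste(rt$resno, rt$insert))
    ai <- match(paste(hb_ch$acceptor_resno, hb_ch$acceptor_insert),
                paste(rt$resno, rt$insert))
    hbset <- paste(di, ai)
    hb <- function(i, j) paste(i, j) %in% hbset
    bridges <- list()
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j - i < 2) next
        if ((hb(i, j) && hb(j, i)) ||
            (i > 1 && j < n && hb(i - 1, j + 1) && hb(j - 1, i + 1))) {
          bridges[[length(bridges) + 1L]] <- c(i, j)
        }
      }
    }
    if (length(bridges) == 0) next
    bm <- do.call(rbind, bridges)
    # merge into antiparallel ladders: bridges (i, j) and (i+1, j-1) chain up
    used <- rep(FALSE, nrow(bm))
    ord <- order(bm[, 1])
    for (s in ord) {
      if (used[s]) next
      i0 <- bm[s, 1]; j0 <- bm[s, 2]
      i1 <- i0; j1 <- j0
      used[s] <- TRUE
      repeat {
        nxt <- which(!used & bm[, 1] == i1 + 1 & bm[, 2] == j1 - 1)
        if (length(nxt) == 0) break
        used[nxt[1]] <- TRUE
        i1 <- i1 + 1; j1 <- j1 - 1
      }
      # strands i0..i1 and j1..j0; loop between i1 and j1
      if (j1 <= i1) next
      loop_len <- j1 - i1 - 1
      if (loop_len < 1 || loop_len > max_loop) next
      if (i1 - i0 + 1 < 2 || j0 - j1 + 1 < 2) next
      twist <- NA_real_
      ca1 <- bb$CA[i0:i1, , drop = FALSE]
      ca2 <- bb$CA[j1:j0, , drop = FALSE]
      if (nrow(ca1) >= 2 && nrow(ca2) >= 2 &&
          !anyNA(ca1) && !anyNA(ca2)) {
        a1 <- strand_axis(ca1); a2 <- strand_axis(ca2)
        twist <- acos(pmin(1, pmax(-1, sum(a1 * a2)))) * 180 / pi
      }
      out[[length(out) + 1L]] <- tibble(
        chain = ch,
        strand1_start = rt$resno[i0], strand1_end = rt$resno[i1],
        strand2_start = rt$resno[j1], strand2_end = rt$resno[j0],
        loop_start = rt$resno[i1 + 1], loop_end = rt$resno[j1 - 1],
        loop_length = loop_len,
        orientation = "antiparallel",
        twist_angle = twist
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chain = character(), strand1_start = integer(),
                  strand1_end = integer(), strand2_start = integer(),
                  strand2_end = integer(), loop_start = integer(),
                  loop_end = integer(), loop_length = integer(),
                  orientation = character(), twist_angle = double()))
  }
  bind_rows(out) |> distinct() |> arrange(.data$chain, .data$strand1_start)
}

#' Classify the loop capping a beta-hairpin
#'
#' Residue `i` is the first residue of the loop span. A 4-residue loop is
#' a beta-turn; a 5-residue loop is a type-1 bulge-loop candidate flagged
#' by the bond N-H(i) -> C=O(i+4); a 6-residue loop is a type-2 candidate
#' flagged by N-H(i) -> C=O(i+5). In relaxed mode (default) the
#' characteristic bond alone decides, and the presence and N..O distance
#' of the second shared bond C=O(i) -> N-H(i+4) are recorded as evidence;
#' strict mode requires both bonds. Anything else is `non_canonical`.
#'
#' @param motif One row of [find_beta_hairpins()] output (or a list with
#'   the same fields).
#' @param structure The `struct_tbl` the motif came from.
#' @param hbonds Output of [backbone_hbonds()]; computed if `NULL`.
#' @param relaxed Require only the first characteristic bond (default
#'   `TRUE`)?
#' @return One-row tibble: `label`, `loop_length`, `residue_i`,
#'   `hb_i_to_i5` / `hb_i_to_i4` presence flags and their N..O distances
#'   (A). Distances are reported whether or not the bond is present.
#' @export
classify_loop <- function(motif, structure, hbonds = NULL, relaxed = TRUE) {
  if (is.data.frame(motif)) {
    stopifnot(nrow(motif) == 1)
    motif <- as.list(motif)
  }
  if (is.null(hbonds)) hbonds <- backbone_hbonds(structure)
  ch <- motif$chain
  bb <- backbone_matrices(structure, ch)
  rt <- bb$residues
  li <- which(rt$resno >= motif$loop_start & rt$resno <= motif$loop_end)
  n_loop <- length(li)
  if (n_loop < 3 || n_loop > 8) {
    abort(paste0("loop length ", n_loop,
                 " is outside the 3-8 residue taxonomy"),
          class = "latchkit_out_of_taxonomy")
  }
  i <- li[1]
  res_i <- rt$resno[i]
  dist_no <- function(don, acc) {
    if (don > nrow(rt) || acc > nrow(rt)) return(NA_real_)
    if (anyNA(bb$N[don, ]) || anyNA(bb$O[acc, ])) return(NA_real_)
    vnorm(bb$N[don, ] - bb$O[acc, ])
  }
  # characteristic bond: N-H(i) -> C=O(i+5) (type 2) / C=O(i+4) (type 1)
  hb_i5 <- has_hbond(hbonds, ch, rt$resno[i], resno_at(rt, i + 5))
  d_i5 <- dist_no(i, i + 5)
  hb_i4_fwd <- has_hbond(hbonds, ch, rt$resno[i], resno_at(rt, i + 4))
  d_i4_fwd <- dist_no(i, i + 4)
  # second shared bond: C=O(i) -> N-H(i+4), i.e. donor i+4, acceptor i
  hb_i4 <- has_hbond(hbonds, ch, resno_at(rt, i + 4), rt$resno[i])
  d_i4 <- dist_no(i + 4, i)
  label <- "non_canonical"
  if (n_loop == 4) {
    label <- "beta_turn"
  } else if (n_loop == 5) {
    ok <- hb_i4_fwd && (relaxed || hb_i4)
    if (ok) label <- "type1_bulge_loop"
  } else if (n_loop == 6) {
    ok <- hb_i5 && (relaxed || hb_i4)
    if (ok) label <- "type2_bulge_loop"
  }
  tibble(
    chain = ch,
    label = label,
    loop_length = n_loop,
    residue_i = res_i,
    hb_i_to_i5 = hb_i5, dist_i_to_i5 = d_i5,
    hb_i_to_i4 = hb_i4, dist_i_to_i4 = d_i4,
    hb_i_nh_to_i4 = hb_i4_fwd, dist_i_nh_to_i4 = d_i4_fwd,
    relaxed = relaxed
  )
}

resno_at <- function(rt, idx) {
  if (idx < 1 || idx > nrow(rt)) return(NA_integer_)
  rt$resno[idx]
}

#' Scan a structure for hairpin motifs and classify each loop
#'
#' Convenience wrapper chaining [backbone_hbonds()],
#' [find_beta_hairpins()] and [classify_loop()].
#'
#' @inheritParams find_beta_hairpins
#' @inheritParams classify_loop
#' @return Tibble with one row per motif: the hairpin geometry columns
#'   plus the classification columns.
#' @export
classify_hairpins <- function(structure, hbonds = NULL, relaxed = TRUE,
                              max_loop = 8) {
  if (is.null(hbonds)) hbonds <- backbone_hbonds(structure)
  motifs <- find_beta_hairpins(structure, hbonds, max_loop = max_loop)
  if (nrow(motifs) == 0) {
    return(dplyr::bind_cols(motifs, classify_empty()))
  }
  cls <- purrr::map(seq_len(nrow(motifs)), function(k) {
    classify_loop(motifs[k, ], structure, hbonds, relaxed = relaxed) |>
      select(-"chain", -"loop_length")
  })
  dplyr::bind_cols(motifs, bind_rows(cls))
}

classify_empty <- function() {
  tibble(label = character(), residue_i = integer(),
         hb_i_to_i5 = logical(), dist_i_to_i5 = double(),
         hb_i_to_i4 = logical(), dist_i_to_i4 = double(),
         hb_i_nh_to_i4 = logical(), dist_i_nh_to_i4 = double(),
         relaxed = logical())
}

#' Loop span of a hairpin defined by strand length
#'
#' Pure bookkeeping for printed regions: given a region span and the
#' strand length at either end, returns the loop span and sequence. For
#' the minimal latch of *T. maritima* reverse gyrase (residues 387-400,
#' sequence `PSMRFSLEELIIPD`, strands of four) this yields the 6-residue
#' loop `FSLEEL` starting at residue 391.
#'
#' @param sequence One-letter sequence of the whole region.
#' @param start Author number of the first region residue.
#' @param strand_length Number of residues in each flanking strand
#'   (default 4).
#' @return One-row tibble: loop start/end (author numbers), length and
#'   sequence.
#' @examples
#' hairpin_loop_span("PSMRFSLEELIIPD", start = 387)
#' @export
hairpin_loop_span <- function(sequence, start = 1L, strand_length = 4L) {
  n <- nchar(sequence)
  if (n <= 2 * strand_length) {
    abort("region shorter than two strands; no loop")
  }
  loop_seq <- substr(sequence, strand_length + 1, n - strand_length)
  tibble(
    loop_start = as.integer(start + strand_length),
    loop_end = as.integer(start + n - strand_length - 1),
    loop_length = n - 2L * as.integer(strand_length),
    loop_sequence = loop_seq
  )
}
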