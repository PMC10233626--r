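# Rigid-body superposition (Kabsch), iterative outlier rejection,
# displacement probes and inter-region heavy-atom contacts.

#' Pair equivalent atoms of two structures
#'
#' Residues are matched between structures by (chain, author number,
#' insertion code) after an optional span restriction; within matched
#' residues, atoms are matched by name. Unmatched residues/atoms are
#' dropped and counted.
#'
#' @param ref,mov `struct_tbl` structures.
#' @param spans Optional span restriction (string or data frame) applied
#'   to both structures.
#' @param atom_mode `"CA"` (default), `"backbone"` (N, CA, C, O) or
#'   `"all_heavy"`.
#' @return Tibble with one row per matched atom: identifiers and the
#'   coordinates in both structures (`x_ref..`, `x_mov..`). Attribute
#'   `n_unmatched` counts entries present on one side only.
#' @export
pair_atoms <- function(ref, mov, spans = NULL,
                       atom_mode = c("CA", "backbone", "all_heavy")) {
  atom_mode <- match.arg(atom_mode)
  keep <- switch(atom_mode,
    CA = function(d) d[d$elety == "CA", , drop = FALSE],
    backbone = function(d) d[d$elety %in% c("N", "CA", "C", "O"), , drop = FALSE],
    all_heavy = function(d) d[d$element != "H", , drop = FALSE]
  )
  a <- keep(if (is.null(spans)) ref else select_region(ref, spans))
  b <- keep(if (is.null(spans)) mov else select_region(mov, spans))
  key <- function(d) paste(d$chain, d$resno, d$insert, d$elety, sep = "\r")
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  if (length(common) == 0) {
    abort("no atoms could be paired between the two structures",
          class = "latchkit_pairing_error")
  }
  ia <- match(common, ka); ib <- match(common, kb)
  pairing <- tibble(
    chain = a$chain[ia], resno = a$resno[ia], insert = a$insert[ia],
    elety = a$elety[ia],
    x_ref = a$x[ia], y_ref = a$y[ia], z_ref = a$z[ia],
    x_mov = b$x[ib], y_mov = b$y[ib], z_mov = b$z[ib]
  ) |> arrange(.data$chain, .data$resno, .data$insert, .data$elety)
  attr(pairing, "n_unmatched") <-
    (length(ka) - length(common)) + (length(kb) - length(common))
  pairing
}

kabsch_fit <- function(P, Q) {
  # optimal rotation R and translation t with R %*% p + t ~ q
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  list(rotation = R, translation = t)
}

new_superposition <- function(rotation, translation, rmsd, pairing,
                              used, residuals) {
  structure(
    list(rotation = rotation, translation = translation, rmsd = rmsd,
         n_atoms_used = sum(used), n_rejected = sum(!used),
         pairing = pairing, used = used, residuals = residuals),
    class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Kabsch superposition: rmsd %.4f A over %d atoms (%d rejected)\n",
              x$rmsd, x$n_atoms_used, x$n_rejected))
  invisible(x)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation/translation minimising the r.m.s.d. between the
#' moving and reference coordinates of an atom pairing, via the
#' singular-value method with reflection correction (det(R) = +1).
#'
#' @param pairing Output of [pair_atoms()].
#' @return A `superposition` object: `rotation` (3x3, applied to the
#'   moving coordinates), `translation`, `rmsd` (A), counts and the
#'   pairing with per-atom residuals. Supports [tidy()] and [glance()].
#' @export
kabsch_superpose <- function(pairing) {
  P <- as.matrix(pairing[, c("x_mov", "y_mov", "z_mov")])
  Q <- as.matrix(pairing[, c("x_ref", "y_ref", "z_ref")])
  if (nrow(P) < 3) abort("need at least 3 paired atoms")
  if (qr(sweep(Q, 2, colMeans(Q)))$rank < 2 ||
      qr(sweep(P, 2, colMeans(P)))$rank < 2) {
    abort("degenerate (collinear or coincident) point set",
          class = "latchkit_degenerate_points")
  }
  f <- kabsch_fit(P, Q)
  Pt <- sweep(P %*% t(f$rotation), 2, f$translation, "+")
  res <- sqrt(rowSums((Pt - Q)^2))
  new_superposition(f$rotation, f$translation, sqrt(mean(res^2)),
                    pairing, used = rep(TRUE, nrow(P)), residuals = res)
}

#' Superposition with iterative outlier rejection
#'
#' Repeats [kabsch_superpose()], dropping pairs whose residual exceeds
#' `reject_cutoff` after each fit, until no pair is rejected or
#' `max_cycles` is reached. The final r.m.s.d. is over retained pairs
#' only. This mirrors the refinement used by molecular-graphics `align`
#' commands whose quoted r.m.s.d.s exclude outliers.
#'
#' @param pairing Output of [pair_atoms()].
#' @param reject_cutoff Residual threshold in A (default 2.0).
#' @param max_cycles Maximum refinement cycles (default 5).
#' @return A `superposition` object; rejected pairs are flagged in
#'   `$used` and counted in `$n_rejected`.
#' @export
refine_superpose <- function(pairing, reject_cutoff = 2.0, max_cycles = 5) {
  keep <- rep(TRUE, nrow(pairing))
  fit <- kabsch_superpose(pairing)
  for (cycle in seq_len(max_cycles)) {
    sub <- pairing[keep, , drop = FALSE]
    if (nrow(sub) < 3) {
      abort("outlier rejection removed (almost) all pairs",
            class = "latchkit_rejection_collapse")
    }
    fit_k <- kabsch_superpose(sub)
    # residuals of *all* pairs under the current fit
    P <- as.matrix(pairing[, c("x_mov", "y_mov", "z_mov")])
    Q <- as.matrix(pairing[, c("x_ref", "y_ref", "z_ref")])
    Pt <- sweep(P %*% t(fit_k$rotation), 2, fit_k$translation, "+")
    res <- sqrt(rowSums((Pt - Q)^2))
    new_keep <- keep & res <= reject_cutoff
    if (!any(new_keep)) {
      abort("outlier rejection removed all pairs",
            class = "latchkit_rejection_collapse")
    }
    done <- identical(new_keep, keep)
    keep <- new_keep
    fit <- new_superposition(fit_k$rotation, fit_k$translation,
                             sqrt(mean(res[keep]^2)), pairing, keep, res)
    if (done) break
  }
  fit
}

#' Apply a superposition to a structure
#'
#' @param structure A `struct_tbl` (typically the moving structure).
#' @param fit A `superposition` object.
#' @return The transformed `struct_tbl`.
#' @export
apply_superposition <- function(structure, fit) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
  structure$x <- xyz[, 1]; structure$y <- xyz[, 2]; structure$z <- xyz[, 3]
  structure
}

#' Displacement of probe atoms after superposition on a fit region
#'
#' Superposes `mov` onto `ref` using the fit selection (with outlier
#' rejection), then reports the distance between each probe atom's
#' position in the two structures in the common frame.
#'
#' @param ref,mov `struct_tbl` structures.
#' @param fit_spans Span restriction defining the fit region.
#' @param probes Data frame with columns `chain`, `resno`, `elety`
#'   (e.g. `tibble(chain = "A", resno = 364, elety = "OH")`).
#' @param atom_mode Atom mode for the fit pairing (default `"CA"`).
#' @param ... Passed to [refine_superpose()].
#' @return `probes` with an added `displacement` column (A; `NA` with a
#'   `missing` flag if the atom is absent from either structure).
#' @export
probe_displacement <- function(ref, mov, fit_spans, probes,
                               atom_mode = "CA", ...) {
  fit <- refine_superpose(pair_atoms(ref, mov, fit_spans, atom_mode), ...)
  mov_t <- apply_superposition(mov, fit)
  find_atom <- function(s, ch, rn, at) {
    hit <- s[s$chain == ch & s$resno == rn & s$elety == at, , drop = FALSE]
    if (nrow(hit) == 0) NULL else as.numeric(hit[1, c("x", "y", "z")])
  }
  probes <- as_tibble(probes)
  out <- purrr::map_dbl(seq_len(nrow(probes)), function(k) {
    p1 <- find_atom(ref, probes$chain[k], probes$resno[k], probes$elety[k])
    p2 <- find_atom(mov_t, probes$chain[k], probes$resno[k], probes$elety[k])
    if (is.null(p1) || is.null(p2)) return(NA_real_)
    vnorm(p1 - p2)
  })
  probes$displacement <- out
  probes$missing <- is.na(out)
  attr(probes, "fit") <- fit
  probes
}

#' Heavy-atom contacts between two regions of a structure
#'
#' Enumerates all heavy-atom pairs across two disjoint residue selections
#' with inter-atomic distance at most `cutoff`.
#'
#' @param structure A `struct_tbl`.
#' @param region_a,region_b Span strings or span data frames; must not
#'   overlap.
#' @param cutoff Distance cutoff in A (default 4.5).
#' @return Tibble of contacting atom pairs (residue/atom identifiers on
#'   both sides plus `distance`), with attributes `residues_a` /
#'   `residues_b` (sorted unique contacting residue numbers) and
#'   `cutoff`.
#' @export
region_contacts <- function(structure, region_a, region_b, cutoff = 4.5) {
  a <- select_region(structure, region_a)
  b <- select_region(structure, region_b)
  key <- function(d) paste(d$chain, d$resno, d$insert)
  if (length(intersect(unique(key(a)), unique(key(b)))) > 0) {
    abort("regions overlap", class = "latchkit_selection_error")
  }
  a <- a[a$element != "H", , drop = FALSE]
  b <- b[b$element != "H", , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("empty region selection", class = "latchkit_selection_error")
  }
  d <- outer_dist(as.matrix(a[, c("x", "y", "z")]),
                  as.matrix(b[, c("x", "y", "z")]))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  pairs <- tibble(
    chain_a = a$chain[hit[, 1]], resno_a = a$resno[hit[, 1]],
    resname_a = a$resname[hit[, 1]], elety_a = a$elety[hit[, 1]],
    chain_b = b$chain[hit[, 2]], resno_b = b$resno[hit[, 2]],
    resname_b = b$resname[hit[, 2]], elety_b = b$elety[hit[, 2]],
    distance = d[hit]
  ) |> arrange(.data$resno_a, .data$resno_b, .data$distance)
  attr(pairs, "residues_a") <- sort(unique(pairs$resno_a))
  attr(pairs, "residues_b") <- sort(unique(pairs$resno_b))
  attr(pairs, "cutoff") <- cutoff
  pairs
}

#' @rdname kabsch_superpose
#' @param x A `superposition` object.
#' @param ... Unused.
#' @export
tidy.superposition <- function(x, ...) {
  dplyr::bind_cols(
    x$pairing[, c("chain", "resno", "insert", "elety")],
    tibble(residual = x$residuals, used = x$used)
  )
}

#' @rdname kabsch_superpose
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_atoms_used = x$n_atoms_used,
         n_rejected = x$n_rejected,
         det_rotation = det(x$rotation))
}
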