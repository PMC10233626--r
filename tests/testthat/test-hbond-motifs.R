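test_that("amide hydrogens follow the Kabsch-Sander placement rule", {
  st <- build_ideal_strand(6)
  sth <- infer_amide_hydrogens(st)
  h <- sth[sth$elety == "H", ]
  expect_equal(nrow(h), 5)           # none on the chain start
  # every H is 1.0 A from its own N, opposite the preceding carbonyl
  for (k in 2:6) {
    hp <- as.numeric(h[h$resno == k, c("x", "y", "z")])
    np <- as.numeric(sth[sth$resno == k & sth$elety == "N", c("x", "y", "z")])
    cp <- as.numeric(sth[sth$resno == k - 1 & sth$elety == "C", c("x", "y", "z")])
    op <- as.numeric(sth[sth$resno == k - 1 & sth$elety == "O", c("x", "y", "z")])
    expect_equal(sqrt(sum((hp - np)^2)), 1.0, tolerance = 1e-6)
    v1 <- (hp - np); v2 <- (cp - op) / sqrt(sum((cp - op)^2))
    expect_equal(v1, v2, tolerance = 1e-6)
  }
})

test_that("prolines receive no amide hydrogen", {
  st <- build_ideal_strand(4)
  st$resname[st$resno == 3] <- "PRO"
  sth <- infer_amide_hydrogens(st)
  expect_false(3 %in% sth$resno[sth$elety == "H"])
  expect_true(all(c(2, 4) %in% sth$resno[sth$elety == "H"]))
})

test_that("residues with a missing preceding carbonyl are skipped with warning", {
  st <- build_ideal_strand(4)
  st <- st[!(st$resno == 2 & st$elety == "O"), ]
  expect_warning(sth <- infer_amide_hydrogens(st), "carbonyl")
  expect_false(3 %in% sth$resno[sth$elety == "H"])
})

test_that("distant residues form no hydrogen bond and cutoff is validated", {
  a <- build_ideal_strand(2)
  b <- build_ideal_strand(2, start = 10L)
  b$x <- b$x + 50
  st <- latchkit:::new_structure_tbl(rbind(a, b))
  hb <- backbone_hbonds(st)
  expect_equal(nrow(hb), 0)
  expect_error(backbone_hbonds(st, energy_cutoff = 0.5), "negative")
})

test_that("the generator's blueprint bonds are detected and energies are rigid-motion invariant", {
  h <- build_hairpin(hairpin_blueprint(loop_length = 6))
  hb <- backbone_hbonds(h$structure)
  bp <- h$blueprint$hbond_blueprint
  for (k in seq_len(nrow(bp))) {
    expect_true(any(hb$donor_resno == bp$donor[k] &
                      hb$acceptor_resno == bp$acceptor[k]),
                info = paste(bp$donor[k], "->", bp$acceptor[k]))
  }
  set.seed(99)
  rr <- random_rigid()
  st2 <- transform_structure(h$structure, rr$R, rr$t)
  hb2 <- backbone_hbonds(st2)
  j <- dplyr::inner_join(hb, hb2,
                         by = c("donor_resno", "acceptor_resno"),
                         suffix = c("", "_t"))
  expect_equal(nrow(j), nrow(hb))
  expect_lt(max(abs(j$energy - j$energy_t)), 1e-9)
})

test_that("an all-helical structure yields no hairpin", {
  helix <- build_ideal_strand(16, phi = -57, psi = -47)
  expect_equal(nrow(find_beta_hairpins(helix)), 0)
})

test_that("synthetic hairpins are found with the blueprint loop length", {
  for (n in c(4, 5, 6)) {
    h <- build_hairpin(hairpin_blueprint(loop_length = n))
    m <- find_beta_hairpins(h$structure)
    expect_equal(nrow(m), 1, info = paste("loop", n))
    expect_equal(m$loop_length, n)
    expect_equal(m$orientation, "antiparallel")
    # loop span excludes strand residues
    expect_equal(m$loop_start, m$strand1_end + 1)
    expect_equal(m$loop_end, m$strand2_start - 1)
  }
})

test_that("classification recovers every blueprint label at zero noise", {
  for (n in c(4, 5, 6)) {
    bp <- hairpin_blueprint(loop_length = n)
    h <- build_hairpin(bp)
    out <- classify_hairpins(h$structure)
    expect_equal(nrow(out), 1)
    expect_equal(out$label, bp$intended_label, info = paste("loop", n))
  }
})

test_that("labels imply loop lengths 4/5/6 exactly", {
  for (n in c(4, 5, 6)) {
    for (s in 1:10) {
      h <- build_hairpin(hairpin_blueprint(n, noise_sigma = 0.15, seed = s))
      out <- try(classify_hairpins(h$structure), silent = TRUE)
      if (inherits(out, "try-error") || nrow(out) == 0) next
      for (k in seq_len(nrow(out))) {
        if (out$label[k] == "beta_turn") expect_equal(out$loop_length[k], 4)
        if (out$label[k] == "type1_bulge_loop") expect_equal(out$loop_length[k], 5)
        if (out$label[k] == "type2_bulge_loop") expect_equal(out$loop_length[k], 6)
      }
    }
  }
})

test_that("strict mode requires both characteristic bonds", {
  h <- build_hairpin(hairpin_blueprint(loop_length = 6))
  hb <- backbone_hbonds(h$structure)
  m <- find_beta_hairpins(h$structure, hb)
  strict <- classify_loop(m[1, ], h$structure, hb, relaxed = FALSE)
  expect_equal(strict$label, "type2_bulge_loop")  # template carries both bonds
  # remove the second bond from the evidence set -> strict demotes,
  # relaxed keeps the label
  i <- strict$residue_i
  hb_drop <- hb[!(hb$donor_resno == i + 4 & hb$acceptor_resno == i), ]
  expect_equal(classify_loop(m[1, ], h$structure, hb_drop, relaxed = FALSE)$label,
               "non_canonical")
  relaxed <- classify_loop(m[1, ], h$structure, hb_drop, relaxed = TRUE)
  expect_equal(relaxed$label, "type2_bulge_loop")
  expect_false(relaxed$hb_i_to_i4)
  expect_gt(relaxed$dist_i_to_i4, 0)  # distance still reported
})

test_that("out-of-taxonomy loops are refused explicitly", {
  h <- build_hairpin(hairpin_blueprint(loop_length = 6))
  m <- find_beta_hairpins(h$structure)
  m$loop_start <- m$loop_start - 3  # pretend a 9-residue loop
  expect_error(classify_loop(m[1, ], h$structure),
               class = "latchkit_out_of_taxonomy")
})

test_that("loop-span bookkeeping reproduces the printed minimal latch", {
  # 387-PSMRFSLEELIIPD-400 with 4-residue strands -> loop FSLEEL (391-396)
  info <- hairpin_loop_span("PSMRFSLEELIIPD", start = 387)
  expect_equal(info$loop_sequence, "FSLEEL")
  expect_equal(info$loop_length, 6)
  expect_equal(info$loop_start, 391L)
  expect_equal(info$loop_end, 396L)
})
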