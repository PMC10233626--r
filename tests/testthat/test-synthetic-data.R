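test_that("ideal strand geometry matches the requested internal coordinates", {
  st <- build_ideal_strand(2)
  expect_equal(nrow(st), 8)
  c1 <- as.numeric(st[st$resno == 1 & st$elety == "C", c("x", "y", "z")])
  n2 <- as.numeric(st[st$resno == 2 & st$elety == "N", c("x", "y", "z")])
  expect_equal(sqrt(sum((c1 - n2)^2)), 1.329, tolerance = 1e-6)
  expect_error(build_ideal_strand(1), "at least 2")
})

test_that("measured phi/psi of a built strand equal the inputs", {
  phi <- -139; psi <- 135
  bb <- latchkit:::build_backbone_matrices(rep(phi, 5), rep(psi, 5))
  ang <- latchkit:::measure_phipsi(bb)
  expect_equal(ang$phi[2:4], rep(phi, 3), tolerance = 1e-4)
  expect_equal(ang$psi[2:4], rep(psi, 3), tolerance = 1e-4)
  # and for a helix
  bbh <- latchkit:::build_backbone_matrices(rep(-57, 5), rep(-47, 5))
  angh <- latchkit:::measure_phipsi(bbh)
  expect_equal(angh$phi[3], -57, tolerance = 1e-4)
  expect_equal(angh$psi[3], -47, tolerance = 1e-4)
})

test_that("internal coordinates are invariant under rigid transformation", {
  st <- build_ideal_strand(5)
  set.seed(123)
  rr <- random_rigid()
  st2 <- transform_structure(st, rr$R, rr$t)
  bb1 <- latchkit:::backbone_matrices(st)
  bb2 <- latchkit:::backbone_matrices(st2)
  a1 <- latchkit:::measure_phipsi(bb1)
  a2 <- latchkit:::measure_phipsi(bb2)
  expect_equal(a1$phi[2:4], a2$phi[2:4], tolerance = 1e-6)
  expect_equal(a1$psi[2:4], a2$psi[2:4], tolerance = 1e-6)
})

test_that("hairpin construction is deterministic under a seed and noisy when asked", {
  h1 <- build_hairpin(hairpin_blueprint(5, noise_sigma = 0.1, seed = 7))
  h2 <- build_hairpin(hairpin_blueprint(5, noise_sigma = 0.1, seed = 7))
  expect_equal(h1$structure$x, h2$structure$x)
  h3 <- build_hairpin(hairpin_blueprint(5, noise_sigma = 0.1, seed = 8))
  expect_false(identical(h1$structure$x, h3$structure$x))
  h0 <- build_hairpin(hairpin_blueprint(5))
  expect_gt(max(abs(h1$structure$x - h0$structure$x)), 0)
  expect_lt(max(abs(h1$structure$x - h0$structure$x)), 0.6)
})

test_that("generator structures round-trip through the PDB reader losslessly", {
  h <- build_hairpin(hairpin_blueprint(6, noise_sigma = 0.05, seed = 3))
  st <- h$structure
  st$x <- round(st$x, 3); st$y <- round(st$y, 3); st$z <- round(st$z, 3)
  f <- tempfile(fileext = ".pdb")
  write_structure_pdb(st, f)
  rd <- read_structure(f)
  expect_equal(nrow(rd), nrow(st))
  expect_equal(rd$elety, st$elety)
  expect_equal(rd$x, st$x)
  # classification agrees before and after the round trip
  expect_equal(classify_hairpins(rd)$label, classify_hairpins(st)$label)
})

test_that("blueprint validation rejects inconsistent requests", {
  expect_error(hairpin_blueprint(7), "loop_length")
  expect_error(seqset_blueprint(sign_composition = c(positive = 1, neutral = 0,
                                                     negative = 0)),
               "sum")
})

test_that("generated sequence sets realize their planted composition exactly", {
  bp <- seqset_blueprint(seed = 42)
  seqs <- generate_sequences(bp)
  expect_equal(nrow(seqs), 184)
  # planted charges equal the formula applied to the emitted sequences
  expect_equal(net_charge(seqs$sequence), seqs$planted_charge)
  cs <- charge_summary(tibble::tibble(id = seqs$id,
                                      region_sequence = seqs$sequence))
  expect_equal(cs$counts$positive, 114)
  expect_equal(cs$counts$neutral, 13)
  expect_equal(cs$counts$negative, 57)
  cl <- cluster_lengths(nchar(seqs$sequence), gap_threshold = 6)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$n, c(3, 36, 145))
  expect_equal(cl$min_length[1], 13)
  expect_true(cl$min_length[2] >= 59 && cl$max_length[2] <= 82)
  expect_true(cl$min_length[3] >= 89 && cl$max_length[3] <= 119)
})

test_that("same seed gives byte-identical FASTA output", {
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(generate_sequences(seqset_blueprint(seed = 5)), f1)
  write_fasta(generate_sequences(seqset_blueprint(seed = 5)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("a single neutral one-residue sequence is generated correctly", {
  bp <- seqset_blueprint(length_clusters = data.frame(min = 1, max = 1, count = 1),
                         sign_composition = c(positive = 0, neutral = 1,
                                              negative = 0),
                         seed = 2)
  s <- generate_sequences(bp)
  expect_equal(nchar(s$sequence), 1)
  expect_equal(net_charge(s$sequence), 0)
})
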