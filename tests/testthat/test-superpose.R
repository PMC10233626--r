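make_cloud_structs <- function(n = 20, seed = 1, noise = 0, displace = NULL) {
  set.seed(seed)
  xyz <- matrix(rnorm(n * 3, 0, 6), n, 3)
  st <- tibble::tibble(
    chain = "A", resno = seq_len(n), insert = "", resname = "ALA",
    elety = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1
  )
  ref <- latchkit:::new_structure_tbl(st, id = "ref")
  mov <- ref
  if (noise > 0) {
    mov$x <- mov$x + rnorm(n, 0, noise)
    mov$y <- mov$y + rnorm(n, 0, noise)
    mov$z <- mov$z + rnorm(n, 0, noise)
  }
  if (!is.null(displace)) {
    for (d in displace) mov[[d$axis]][d$idx] <- mov[[d$axis]][d$idx] + d$by
  }
  rr <- random_rigid()
  list(ref = ref, mov = transform_structure(mov, rr$R, rr$t), rigid = rr)
}

test_that("superposing a structure on itself gives rmsd zero", {
  cl <- make_cloud_structs(seed = 3)
  pr <- pair_atoms(cl$ref, cl$ref, atom_mode = "CA")
  expect_equal(nrow(pr), 20)
  fit <- kabsch_superpose(pr)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
})

test_that("a rigidly moved copy is recovered exactly", {
  for (seed in 1:5) {
    cl <- make_cloud_structs(seed = seed)
    pr <- pair_atoms(cl$ref, cl$mov, atom_mode = "CA")
    fit <- kabsch_superpose(pr)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # recovered rotation undoes the applied one
    expect_equal(fit$rotation %*% cl$rigid$R, diag(3), tolerance = 1e-6)
  }
})

test_that("kabsch rmsd matches the rotation-grid brute-force minimum", {
  for (seed in c(2, 9)) {
    cl <- make_cloud_structs(seed = seed, noise = 1.0)
    pr <- pair_atoms(cl$ref, cl$mov, atom_mode = "CA")
    fit <- kabsch_superpose(pr)
    P <- as.matrix(pr[, c("x_mov", "y_mov", "z_mov")])
    Q <- as.matrix(pr[, c("x_ref", "y_ref", "z_ref")])
    oracle <- grid_rmsd_oracle(P, Q)
    expect_gte(oracle, fit$rmsd - 1e-9)  # oracle cannot beat the optimum
    expect_lt(abs(oracle - fit$rmsd), 1e-3)
  }
})

test_that("rmsd is symmetric and invariant under rigid pre-transformation", {
  cl <- make_cloud_structs(seed = 5, noise = 0.8)
  pr_ab <- pair_atoms(cl$ref, cl$mov, atom_mode = "CA")
  pr_ba <- pair_atoms(cl$mov, cl$ref, atom_mode = "CA")
  expect_equal(kabsch_superpose(pr_ab)$rmsd, kabsch_superpose(pr_ba)$rmsd,
               tolerance = 1e-9)
  rr <- random_rigid()
  mov2 <- transform_structure(cl$mov, rr$R, rr$t)
  pr2 <- pair_atoms(cl$ref, mov2, atom_mode = "CA")
  expect_equal(kabsch_superpose(pr2)$rmsd, kabsch_superpose(pr_ab)$rmsd,
               tolerance = 1e-9)
})

test_that("degenerate point sets are rejected", {
  st <- tibble::tibble(
    chain = "A", resno = 1:5, insert = "", resname = "ALA",
    elety = "CA", element = "C",
    x = as.numeric(1:5), y = 0, z = 0, occupancy = 1)
  line <- latchkit:::new_structure_tbl(st, id = "line")
  pr <- pair_atoms(line, line, atom_mode = "CA")
  expect_error(kabsch_superpose(pr), class = "latchkit_degenerate_points")
})

test_that("outlier rejection removes planted outliers and lowers rmsd", {
  cl <- make_cloud_structs(
    n = 30, seed = 8, noise = 0.3,
    displace = list(list(axis = "x", idx = c(3, 11, 27), by = 8)))
  pr <- pair_atoms(cl$ref, cl$mov, atom_mode = "CA")
  plain <- kabsch_superpose(pr)
  ref <- refine_superpose(pr, reject_cutoff = 2.0)
  expect_equal(ref$n_rejected, 3)
  expect_setequal(tidy(ref)$resno[!tidy(ref)$used], c(3, 11, 27))
  expect_lt(ref$rmsd, plain$rmsd)             # monotone under rejection
  expect_lt(ref$rmsd, 0.8)                    # ~ noise level
  expect_equal(ref$n_atoms_used + ref$n_rejected, nrow(pr))
  # clean clouds are untouched
  cl2 <- make_cloud_structs(seed = 12, noise = 0.2)
  pr2 <- pair_atoms(cl2$ref, cl2$mov, atom_mode = "CA")
  expect_equal(refine_superpose(pr2)$rmsd, kabsch_superpose(pr2)$rmsd)
})

test_that("pairing honours selections, gaps and atom modes", {
  a <- ideal_chain(100)
  b <- select_region(a, tibble::tibble(chain = "A", start = c(1, 62), end = c(30, 100)))
  pr <- pair_atoms(a, b, atom_mode = "CA")
  expect_equal(nrow(pr), 69)                  # 31..61 missing from b
  expect_false(any(pr$resno %in% 31:61))
  pr_bb <- pair_atoms(a, b, atom_mode = "backbone")
  expect_equal(nrow(pr_bb), 69 * 4)
  expect_error(pair_atoms(select_region(a, "A:1-10"),
                          select_region(a, "A:50-60")),
               class = "latchkit_pairing_error")
})

test_that("insertion codes are matched, not silently aligned", {
  a <- ideal_chain(5)
  b <- a
  b$insert[b$resno == 3] <- "A"   # 3A on one side only
  pr <- pair_atoms(a, b, atom_mode = "CA")
  expect_equal(nrow(pr), 4)
  expect_equal(attr(pr, "n_unmatched"), 2)
})

test_that("probe displacement reports planted shifts after fitting", {
  base <- ideal_chain(40)
  mov <- base
  sel <- mov$resno == 40
  mov$x[sel] <- mov$x[sel] + 7.5  # translate one residue off before the rigid move
  set.seed(21)
  rr <- random_rigid()
  mov <- transform_structure(mov, rr$R, rr$t)
  probes <- tibble::tibble(chain = "A", resno = c(40, 1), elety = c("CA", "CA"))
  pd <- probe_displacement(base, mov, "A:1-39", probes, atom_mode = "CA")
  expect_equal(pd$displacement[1], 7.5, tolerance = 1e-6)
  expect_equal(pd$displacement[2], 0, tolerance = 1e-6)
  # missing probe atom flags, not fails
  probes2 <- tibble::tibble(chain = "A", resno = 40, elety = "OH")
  pd2 <- probe_displacement(base, mov, "A:1-39", probes2)
  expect_true(pd2$missing[1])
})

test_that("contacts respect cutoffs, disjointness and monotonicity", {
  # two residues 3.5 A apart, third 10 A away
  st <- tibble::tibble(
    chain = "A", resno = c(1, 2, 3), insert = "", resname = "ALA",
    elety = "CA", element = "C",
    x = c(0, 3.5, 13.5), y = 0, z = 0, occupancy = 1)
  st <- latchkit:::new_structure_tbl(st)
  ct <- region_contacts(st, "A:1-1", "A:2-3", cutoff = 4.5)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$distance, 3.5)
  expect_equal(attr(ct, "residues_b"), 2)
  ct0 <- region_contacts(st, "A:1-1", "A:3-3", cutoff = 4.5)
  expect_equal(nrow(ct0), 0)
  expect_error(region_contacts(st, "A:1-2", "A:2-3"),
               class = "latchkit_selection_error")
  # monotone non-decreasing in cutoff
  set.seed(4)
  big <- ideal_chain(60)
  n1 <- nrow(region_contacts(big, "A:1-20", "A:30-60", cutoff = 4))
  n2 <- nrow(region_contacts(big, "A:1-20", "A:30-60", cutoff = 6))
  n3 <- nrow(region_contacts(big, "A:1-20", "A:30-60", cutoff = 8))
  expect_true(n1 <= n2 && n2 <= n3)
})
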