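test_that("net charge follows the pH-7 counting formula", {
  expect_equal(net_charge(""), 0)
  expect_equal(net_charge("KRH"), 2.5)
  # hand counts for the two printed latch sequences:
  # PSMRFSLEELIIPD: R=1, D=1, E=2 -> 1 - 3 = -2
  # PKFRIEKEDLILPD: K=2, R=1, D=2, E=2 -> 3 - 4 = -1
  expect_equal(net_charge("PSMRFSLEELIIPD"), -2)
  expect_equal(net_charge("PKFRIEKEDLILPD"), -1)
  expect_warning(net_charge("AB1"), "unknown")
})

test_that("net charge is additive under concatenation", {
  set.seed(42)
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (k in 1:25) {
    s <- paste(sample(alphabet, sample(0:30, 1), replace = TRUE), collapse = "")
    t <- paste(sample(alphabet, sample(0:30, 1), replace = TRUE), collapse = "")
    expect_equal(net_charge(paste0(s, t)), net_charge(s) + net_charge(t))
  }
})

test_that("hydrophobicity is the mean Kyte-Doolittle value", {
  expect_equal(hydrophobicity_index("I"), 4.5)
  expect_equal(hydrophobicity_index("IR"), 0)
  # mean over the printed minimal-latch sequence, summed by hand from the
  # published scale values
  kd <- c(P = -1.6, S = -0.8, M = 1.9, R = -4.5, F = 2.8, S = -0.8,
          L = 3.8, E = -3.5, E = -3.5, L = 3.8, I = 4.5, I = 4.5,
          P = -1.6, D = -3.5)
  expect_equal(hydrophobicity_index("PSMRFSLEELIIPD"), mean(kd))
  expect_error(hydrophobicity_index(""), "empty")
  expect_error(hydrophobicity_index("AA", scale = "nope"), "unknown")
})

test_that("length clustering splits at gaps and is order-invariant", {
  one <- cluster_lengths(c(13, 13, 13))
  expect_equal(nrow(one), 1)
  expect_equal(one$n, 3)
  expect_equal(one$min_length, 13)
  x <- c(13, 13, 13, 59, 63, 68, 74, 79, 82, 89, 95, 100, 106, 112, 118)
  cl <- cluster_lengths(x, gap_threshold = 6)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$n, c(3L, 6L, 6L))
  expect_equal(cl$min_length, c(13L, 59L, 89L))
  expect_equal(cl$max_length, c(13L, 82L, 118L))
  expect_equal(sum(cl$n), length(x))
  cl2 <- cluster_lengths(sample(x), gap_threshold = 6)
  expect_equal(cl, cl2)
})

test_that("alignment regions map through gaps correctly", {
  # gapless: identical spans
  msa <- tibble::tibble(id = c("r", "s"),
                        sequence = c("ACDEFG", "ACDEFG"))
  reg <- map_alignment_region(msa, "r", 3, 5)
  expect_equal(reg$region_sequence, c("DEF", "DEF"))
  expect_equal(reg$start, c(3L, 3L))
  expect_equal(reg$end, c(5L, 5L))
  # internal deletion in the second sequence shortens its region
  ref <- paste(rep("A", 100), collapse = "")
  del <- paste(c(rep("A", 20), rep("-", 61), rep("A", 19)), collapse = "")
  msa2 <- tibble::tibble(id = c("r", "s"), sequence = c(ref, del))
  reg2 <- map_alignment_region(msa2, "r", 10, 90)
  expect_equal(reg2$length, c(81L, 81L - 61L))
  # errors: absent reference, out-of-range positions
  expect_error(map_alignment_region(msa, "zz", 1, 2), "not in alignment")
  expect_error(map_alignment_region(msa, "r", 1, 99), "only")
})

test_that("all-gap regions are allowed and reported with zero length", {
  msa <- tibble::tibble(id = c("r", "s"),
                        sequence = c("ACDEFG", "AC---G"))
  reg <- map_alignment_region(msa, "r", 3, 5)
  expect_equal(reg$length, c(3L, 0L))
  expect_true(is.na(reg$start[2]))
})

test_that("smith_waterman scores identical sequences at 100/100", {
  r <- smith_waterman("PSMRFSLEELIIPD", "PSMRFSLEELIIPD")
  expect_equal(r$percent_identity, 100)
  expect_equal(r$percent_similarity, 100)
  expect_equal(r$aligned_a, "PSMRFSLEELIIPD")
  expect_error(smith_waterman("", "A"), "non-empty")
  expect_error(smith_waterman("AA", "AA", matrix = "NOPE"), "unknown")
})

test_that("smith_waterman equals the brute-force enumeration on small cases", {
  set.seed(33)
  alpha <- c("A", "R", "E")
  for (k in 1:200) {
    a <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    imp <- smith_waterman(a, b)$score
    orc <- latchkit:::sw_score_bruteforce(a, b)
    expect_equal(imp, orc, info = paste(a, b))
  }
})

test_that("smith_waterman score is symmetric and identity <= similarity", {
  set.seed(9)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:20) {
    a <- paste(sample(alpha, sample(5:40, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(5:40, 1), replace = TRUE), collapse = "")
    r1 <- smith_waterman(a, b)
    r2 <- smith_waterman(b, a)
    expect_equal(r1$score, r2$score)
    expect_lte(r1$percent_identity, r1$percent_similarity)
    expect_lte(r1$percent_similarity, 100)
    expect_equal(nchar(r1$aligned_a), nchar(r1$aligned_b))
  }
})

test_that("alignment scores agree with Biostrings as an independent check", {
  skip_if_not_installed("Biostrings")
  set.seed(14)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (k in 1:10) {
    a <- paste(sample(alpha, 30, replace = TRUE), collapse = "")
    b <- paste(sample(alpha, 25, replace = TRUE), collapse = "")
    mine <- smith_waterman(a, b)$score
    bs <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    expect_equal(mine, as.numeric(bs))
  }
})

test_that("charge summary partitions regions by sign", {
  cs <- charge_summary(c("KK", "AA", "DDK"))
  expect_equal(as.numeric(cs$counts), c(1, 1, 1))
  one <- charge_summary("PSMRFSLEELIIPD")
  expect_equal(one$table$charge_class, "negative")
  expect_equal(one$table$charge_per_length, -2 / 14)
})

test_that("clustal and fasta readers agree on a round trip", {
  seqs <- tibble::tibble(id = c("a", "b"),
                         sequence = c("ACDE-FG", "ACD--FG"))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  rd <- read_sequences(fa)
  expect_equal(rd$sequence, seqs$sequence)
  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.8) multiple sequence alignment", "",
               "a    ACDE-FG 6", "b    ACD--FG 5"), cl)
  rc <- read_sequences(cl)
  expect_equal(rc$sequence, seqs$sequence)
  expect_equal(rc$id, seqs$id)
})
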