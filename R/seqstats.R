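# Latch-region sequence statistics: alignment-region mapping, the pH-7
# charge approximation, hydrophobicity, length clustering and
# Smith-Waterman identity/similarity.

#' Read sequences or a multiple alignment into a tibble
#'
#' FASTA and Clustal formats are supported; the result has one row per
#' sequence with columns `id` and `sequence` (gapped, if the input is an
#' alignment).
#'
#' @param path File path.
#' @param format `"auto"` (default; Clustal if the first non-blank line
#'   starts with `CLUSTAL`), `"fasta"` or `"clustal"`.
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    first <- readLines(path, n = 25, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) > 0 && grepl("^CLUSTAL", first[1])) "clustal"
              else "fasta"
  }
  if (format == "fasta") {
    x <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(x))
    return(tibble(id = ids, sequence = unname(as.character(x))))
  }
  # Clustal: blocks of "name  chunk" lines, consensus lines ignored
  lines <- readLines(path, warn = FALSE)
  lines <- lines[-1]
  seqs <- list()
  for (ln in lines) {
    if (!grepl("^\\S+\\s+\\S", ln)) next
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.~-]+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (length(m) == 0) next
    id <- m[2]; chunk <- gsub("[.~]", "-", m[3])
    seqs[[id]] <- paste0(seqs[[id]] %||% "", chunk)
  }
  if (length(seqs) == 0) abort(paste0("no sequences parsed from '", path, "'"))
  tibble(id = names(seqs), sequence = toupper(unlist(seqs, use.names = FALSE)))
}

#' Map a reference residue range through an alignment
#'
#' Given a multiple alignment and a residue range of a reference sequence
#' (1-based, ungapped numbering), finds the corresponding alignment
#' columns and extracts, for every sequence, the ungapped region between
#' those columns (inclusive). This is how latch regions are defined from
#' the positions of the first and last latch residues of a reference
#' crystal structure.
#'
#' @param msa Tibble with columns `id`, `sequence` (gapped), e.g. from
#'   [read_sequences()].
#' @param reference_id `id` of the reference sequence.
#' @param ref_start,ref_end Residue positions in the ungapped reference.
#' @return Tibble with one row per sequence: `id`, `region_sequence`,
#'   `start`, `end` (1-based ungapped positions in that sequence; `NA`
#'   for all-gap regions) and `length`.
#' @export
map_alignment_region <- function(msa, reference_id, ref_start, ref_end) {
  stopifnot(ref_start >= 1, ref_end >= ref_start)
  ri <- which(msa$id == reference_id)
  if (length(ri) == 0) {
    abort(paste0("reference id '", reference_id, "' not in alignment"))
  }
  ref <- strsplit(msa$sequence[ri[1]], "")[[1]]
  is_res <- ref != "-"
  pos <- cumsum(is_res)
  if (ref_end > max(pos)) {
    abort(paste0("reference has only ", max(pos), " residues"))
  }
  col_start <- match(ref_start, pos * is_res)
  col_end <- match(ref_end, pos * is_res)
  if (is.na(col_start) || is.na(col_end)) {
    abort("reference positions fall on a gap column")  # cannot happen for is_res columns
  }
  purrr::map_dfr(seq_len(nrow(msa)), function(k) {
    s <- strsplit(msa$sequence[k], "")[[1]]
    if (length(s) != length(ref)) {
      abort(paste0("sequence '", msa$id[k], "' has a different alignment length"))
    }
    win <- s[col_start:col_end]
    region <- paste(win[win != "-"], collapse = "")
    n_before <- sum(s[seq_len(col_start - 1)] != "-")
    len <- nchar(region)
    tibble(
      id = msa$id[k],
      region_sequence = region,
      start = if (len > 0) n_before + 1L else NA_integer_,
      end = if (len > 0) n_before + len else NA_integer_,
      length = len
    )
  })
}

#' Net charge of a sequence at pH 7
#'
#' The approximation used throughout: number of Arg/Lys plus half the
#' number of His (pKa about 6.5) minus the number of Asp/Glu. Letters
#' outside the 20-residue alphabet contribute zero (with a warning,
#' except for `X` and gaps).
#'
#' @param sequence Character vector of one-letter sequences.
#' @return Numeric vector of net charges (elementary charges).
#' @examples
#' net_charge("PSMRFSLEELIIPD")  # -2
#' net_charge("KRH")             # 2.5
#' @export
net_charge <- function(sequence) {
  vapply(sequence, function(s) {
    if (nchar(s) == 0) return(0)
    ch <- strsplit(toupper(s), "")[[1]]
    ch <- ch[ch != "-"]
    aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y")
    unknown <- setdiff(ch, c(aa20, "X"))
    if (length(unknown) > 0) {
      warn(paste0("unknown letter(s) treated as uncharged: ",
                  paste(unique(unknown), collapse = "")))
    }
    v <- CHARGE_AT_PH7[ch]
    sum(v, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mean hydrophobicity of a sequence
#'
#' Arithmetic mean of per-residue values under a named scale (default
#' Kyte-Doolittle). Letters without a scale value (e.g. `X`) are ignored.
#'
#' @param sequence Character vector of one-letter sequences (non-empty).
#' @param scale Scale name; currently `"kyte_doolittle"`.
#' @return Numeric vector of mean scale values.
#' @examples
#' hydrophobicity_index("I")   # 4.5
#' hydrophobicity_index("IR")  # 0
#' @export
hydrophobicity_index <- function(sequence, scale = "kyte_doolittle") {
  if (!scale %in% names(HYDROPHOBICITY_SCALES)) {
    abort(paste0("unknown hydrophobicity scale '", scale, "'"))
  }
  sc <- HYDROPHOBICITY_SCALES[[scale]]
  vapply(sequence, function(s) {
    if (nchar(s) == 0) abort("empty sequence has no hydrophobicity")
    v <- sc[strsplit(toupper(s), "")[[1]]]
    mean(v, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Cluster region lengths by gaps in their sorted distribution
#'
#' Sorts the lengths and splits wherever two consecutive sorted values
#' differ by more than `gap_threshold` residues. With the default
#' threshold of 6 (one more than a 5-residue histogram bin), the latch
#' survey's three length groups separate cleanly.
#'
#' @param lengths Integer vector of region lengths (at least one).
#' @param gap_threshold Split threshold in residues (default 6).
#' @return Tibble with one row per cluster: `cluster`, `min_length`,
#'   `max_length`, `n`.
#' @export
cluster_lengths <- function(lengths, gap_threshold = 6) {
  if (length(lengths) == 0) abort("need at least one length")
  x <- sort(as.integer(lengths))
  brk <- which(diff(x) > gap_threshold)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(x))
  tibble(
    cluster = seq_along(starts),
    min_length = x[starts],
    max_length = x[ends],
    n = ends - starts + 1L
  )
}

sub_matrix <- function(name) {
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (is.matrix(name)) return(name)
  if (!name %in% known) {
    abort(paste0("unknown substitution matrix '", name, "'"))
  }
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Smith-Waterman local alignment with identity/similarity
#'
#' Optimal local alignment under affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`). Defaults follow EMBOSS `water`:
#' BLOSUM62, open 10, extend 0.5. Percent identity is the fraction of
#' identical columns over the alignment length (gaps included); percent
#' similarity counts columns whose substitution score is positive. Both
#' are rounded to one decimal.
#'
#' @param seq_a,seq_b One-letter sequences (non-empty).
#' @param matrix Substitution matrix name (a Biostrings matrix such as
#'   `"BLOSUM62"`) or a numeric matrix with single-letter dimnames.
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @return One-row tibble: `score`, `aligned_a`, `aligned_b`,
#'   `percent_identity`, `percent_similarity`, `alignment_length`.
#' @examples
#' smith_waterman("PSMRFSLEELIIPD", "PKFRIEKEDLILPD")
#' @export
smith_waterman <- function(seq_a, seq_b, matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) abort("sequences must be non-empty")
  S <- sub_matrix(matrix)
  r <- sw_align_cpp(toupper(seq_a), toupper(seq_b), S, gap_open, gap_extend)
  a <- strsplit(r$aligned_a, "")[[1]]
  b <- strsplit(r$aligned_b, "")[[1]]
  len <- length(a)
  if (len == 0) {
    return(tibble(score = r$score, aligned_a = "", aligned_b = "",
                  percent_identity = 0, percent_similarity = 0,
                  alignment_length = 0L))
  }
  ident <- sum(a == b & a != "-")
  both <- a != "-" & b != "-"
  simil <- sum(S[cbind(a[both], b[both])] > 0)
  tibble(
    score = r$score,
    aligned_a = r$aligned_a, aligned_b = r$aligned_b,
    percent_identity = round(100 * ident / len, 1),
    percent_similarity = round(100 * simil / len, 1),
    alignment_length = as.integer(len)
  )
}

# score-only batch interface (used for oracles and surveys)
smith_waterman_scores <- function(seq_a, seq_b, matrix = "BLOSUM62",
                                  gap_open = 10, gap_extend = 0.5) {
  S <- sub_matrix(matrix)
  sw_scores_pairs_cpp(toupper(seq_a), toupper(seq_b), S, gap_open, gap_extend)
}

# brute-force reference scorer (exhaustive enumeration over matched-column
# sets, memoized); independent of the Gotoh implementation above
sw_score_bruteforce <- function(seq_a, seq_b, matrix = "BLOSUM62",
                                gap_open = 10, gap_extend = 0.5) {
  S <- sub_matrix(matrix)
  sw_score_enum_cpp(toupper(seq_a), toupper(seq_b), S, gap_open, gap_extend)
}

#' Exhaustive cross-check of the local-alignment implementation
#'
#' Compares the Gotoh dynamic-programming scorer used by
#' [smith_waterman()] against an independent brute-force reference that
#' enumerates all matched-column sets, over *every* pair of sequences up
#' to `max_len` over the given alphabet.
#'
#' @param alphabet Character vector of letters (default `c("A","R","E")`).
#' @param max_len Longest sequence length enumerated (default 6).
#' @param matrix,gap_open,gap_extend As in [smith_waterman()].
#' @return List with `max_abs_diff` (should be 0) and `n_pairs`.
#' @export
sw_bruteforce_check <- function(alphabet = c("A", "R", "E"), max_len = 6,
                                matrix = "BLOSUM62", gap_open = 10,
                                gap_extend = 0.5) {
  S <- sub_matrix(matrix)
  seqs <- unlist(purrr::map(seq_len(max_len), function(l) {
    g <- do.call(expand.grid, rep(list(alphabet), l))
    do.call(paste0, g)
  }))
  res <- sw_compare_all_pairs_cpp(seqs, S, gap_open, gap_extend)
  res$n_sequences <- length(seqs)
  res
}

#' Summarise charge classes of latch regions
#'
#' Computes the net charge of every region, partitions the set into
#' positive / electroneutral / negative, and returns per-region values.
#'
#' @param regions Tibble with columns `id` and `region_sequence` (e.g.
#'   from [map_alignment_region()]), or a character vector of sequences.
#' @return List with `table` (per-region tibble: id, length, charge,
#'   charge_per_length, hydrophobicity) and `counts` (one-row tibble of
#'   class counts).
#' @export
charge_summary <- function(regions) {
  if (is.character(regions)) {
    regions <- tibble(id = paste0("seq", seq_along(regions)),
                      region_sequence = regions)
  }
  if (nrow(regions) == 0) abort("no regions given")
  tab <- regions |>
    mutate(
      length = nchar(.data$region_sequence),
      charge = net_charge(.data$region_sequence),
      charge_per_length = ifelse(.data$length > 0,
                                 .data$charge / .data$length, NA_real_),
      hydrophobicity = ifelse(.data$length > 0,
                              hydrophobicity_index(.data$region_sequence),
                              NA_real_),
      charge_class = dplyr::case_when(
        .data$charge > 0 ~ "positive",
        .data$charge < 0 ~ "negative",
        TRUE ~ "neutral"
      )
    ) |>
    select("id", "region_sequence", "length", "charge",
           "charge_per_length", "hydrophobicity", "charge_class")
  counts <- tibble(
    positive = sum(tab$charge_class == "positive"),
    neutral = sum(tab$charge_class == "neutral"),
    negative = sum(tab$charge_class == "negative")
  )
  list(table = tab, counts = counts)
}
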