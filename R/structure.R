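# Structure container: a tidy atom table.
#
# A structure is a tibble with one row per atom and columns
#   chain, resno, insert, resname, elety, element, x, y, z, occupancy
# plus attributes `id` and `source_format`. Author residue numbering is
# preserved as-is; (chain, resno, insert) identifies a residue.

new_structure_tbl <- function(atoms, id = "structure", source_format = "r") {
  atoms <- as_tibble(atoms)
  needed <- c("chain", "resno", "insert", "resname", "elety", "element",
              "x", "y", "z", "occupancy")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  attr(atoms, "id") <- id
  attr(atoms, "source_format") <- source_format
  class(atoms) <- unique(c("struct_tbl", class(atoms)))
  atoms
}

#' @export
print.struct_tbl <- function(x, ...) {
  cat(sprintf("# structure '%s' (%s): %d atoms, %d residues, chains: %s\n",
              structure_id(x), attr(x, "source_format") %||% "?",
              nrow(x), nrow(residue_table(x)),
              paste(unique(x$chain), collapse = ", ")))
  NextMethod()
}

#' Structure identifier
#' @param structure A structure atom table from [read_structure()].
#' @return Character scalar.
#' @export
structure_id <- function(structure) attr(structure, "id") %||% "structure"

element_from_elety <- function(elety) {
  e <- sub("^[0-9']*", "", toupper(elety))
  two <- c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE", "NI", "CO", "CA")
  # atom names are left-padded in PDB; after bio3d trimming, a two-character
  # chemical symbol is only assumed for known metals/halogens to avoid
  # mistaking CA (alpha carbon) or CD for calcium/cadmium
  ifelse(nchar(e) >= 2 & substr(e, 1, 2) %in% setdiff(two, c("CA", "CO")) ,
         substr(e, 1, 2), substr(e, 1, 1))
}

#' Read a macromolecular structure into a tidy atom table
#'
#' Reads PDB or mmCIF coordinates (via \pkg{bio3d}) into a tibble with one
#' row per atom. Only the first model of multi-model files is kept.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties favour altloc `"A"`). Waters and other heteroatoms are excluded
#' by default so residue counts refer to polymer residues.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @param format `"auto"` (default, by file extension), `"pdb"` or `"mmcif"`.
#' @param keep_hetero Keep HETATM records (waters are always dropped)?
#' @param id Identifier stored on the returned table; defaults to the file
#'   base name.
#' @return A `struct_tbl` tibble of atoms.
#' @examples
#' pdb <- build_hairpin(hairpin_blueprint(loop_length = 6))$structure
#' f <- tempfile(fileext = ".pdb")
#' write_structure_pdb(pdb, f)
#' s <- read_structure(f)
#' nrow(residue_table(s))
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hetero = FALSE, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb", cif = "mmcif", mmcif = "mmcif",
      abort(paste0("cannot infer structure format from extension '.", ext,
                   "'; pass format explicitly")))
  }
  obj <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) abort(paste0("failed to parse ", format, " file '",
                                     path, "': ", conditionMessage(e))))
  a <- as_tibble(obj$atom)
  a$insert[is.na(a$insert) | a$insert == ""] <- ""
  a$alt[is.na(a$alt) | a$alt == ""] <- ""
  a$chain[is.na(a$chain)] <- " "
  if (!keep_hetero) a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[a$resid != "HOH", , drop = FALSE]
  if (nrow(a) == 0) abort(paste0("no atoms retained from '", path, "'"))
  a$occupancy <- ifelse(is.na(a$o), 1, a$o)
  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties -> lowest altloc letter (i.e. 'A' before 'B'), '' sorts first
  a <- a |>
    mutate(.ord = order(order(.data$chain, .data$resno, .data$insert,
                              .data$elety, -.data$occupancy, .data$alt))) |>
    arrange(.data$chain, .data$resno, .data$insert, .data$elety,
            -.data$occupancy, .data$alt) |>
    distinct(.data$chain, .data$resno, .data$insert, .data$elety,
             .keep_all = TRUE)
  # restore file order
  a <- a[order(a$eleno), , drop = FALSE]
  atoms <- tibble(
    chain = a$chain, resno = as.integer(a$resno), insert = a$insert,
    resname = a$resid, elety = a$elety,
    element = if ("elesy" %in% names(a) && !all(is.na(a$elesy)))
      ifelse(is.na(a$elesy) | a$elesy == "", element_from_elety(a$elety),
             toupper(a$elesy))
    else element_from_elety(a$elety),
    x = a$x, y = a$y, z = a$z, occupancy = a$occupancy
  )
  new_structure_tbl(atoms,
                    id = id %||% tools::file_path_sans_ext(basename(path)),
                    source_format = if (format == "pdb") "pdb" else "mmcif")
}

#' One row per residue of a structure
#'
#' @param structure A `struct_tbl`.
#' @return Tibble with chain, resno, insert, resname, one-letter code,
#'   atom count and a backbone-completeness flag (N, CA, C, O all present).
#' @export
residue_table <- function(structure) {
  structure |>
    group_by(.data$chain, .data$resno, .data$insert) |>
    summarise(
      resname = .data$resname[1],
      one_letter = aa321(.data$resname[1]),
      n_atoms = n(),
      backbone_complete = all(c("N", "CA", "C", "O") %in% .data$elety),
      .groups = "drop"
    ) |>
    arrange(.data$chain, .data$resno, .data$insert)
}

#' Parse a span string into a span table
#'
#' Spans are written `"A:387-400"` (chain `A`, author numbers 387..400,
#' inclusive); several spans are comma-separated. `"A:400"` is a single
#' residue; `"A:*"` selects the whole chain.
#'
#' @param spec Span string, or a data frame with columns
#'   `chain`, `start`, `end` (returned unchanged).
#' @return Tibble with columns `chain`, `start`, `end`.
#' @examples
#' parse_spans("A:387-400,A:460-500")
#' @export
parse_spans <- function(spec) {
  if (is.data.frame(spec)) {
    stopifnot(all(c("chain", "start", "end") %in% names(spec)))
    return(as_tibble(spec[c("chain", "start", "end")]))
  }
  parts <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  rows <- purrr::map(parts, function(p) {
    m <- regmatches(p, regexec("^([^:]+):(\\*|-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
    if (length(m) == 0) abort(paste0("cannot parse span '", p, "'"))
    if (m[3] == "*") return(tibble(chain = m[2], start = -Inf, end = Inf))
    s <- as.numeric(m[3]); e <- if (m[4] == "") s else as.numeric(m[4])
    if (s > e) abort(paste0("span start > end in '", p, "'"))
    tibble(chain = m[2], start = s, end = e)
  })
  bind_rows(rows)
}

#' Select residues of a structure by author-numbered spans
#'
#' @param structure A `struct_tbl`.
#' @param spans A span string (see [parse_spans()]) or span data frame;
#'   `NULL` selects everything.
#' @param atoms Optional character vector of atom names to keep
#'   (e.g. `"CA"`).
#' @param complement If `TRUE`, return all residues *not* covered by the
#'   spans (chain-restricted to chains named in the spans).
#' @return A `struct_tbl` with the selected atoms, in span order for
#'   `complement = FALSE`.
#' @export
select_region <- function(structure, spans = NULL, atoms = NULL,
                          complement = FALSE) {
  out <- structure
  if (!is.null(spans)) {
    sp <- parse_spans(spans)
    bad <- setdiff(sp$chain, unique(structure$chain))
    if (length(bad) > 0) {
      abort(paste0("span references missing chain(s): ",
                   paste(bad, collapse = ", ")))
    }
    hit <- rep(FALSE, nrow(structure))
    for (k in seq_len(nrow(sp))) {
      hit <- hit | (structure$chain == sp$chain[k] &
                      structure$resno >= sp$start[k] &
                      structure$resno <= sp$end[k])
    }
    out <- if (complement) {
      structure[!hit & structure$chain %in% sp$chain, , drop = FALSE]
    } else {
      # span order: concatenate spans in the order given
      picked <- purrr::map(seq_len(nrow(sp)), function(k) {
        structure[structure$chain == sp$chain[k] &
                    structure$resno >= sp$start[k] &
                    structure$resno <= sp$end[k], , drop = FALSE]
      })
      picked <- bind_rows(picked) |> distinct()
      if (nrow(picked) == 0) structure[0, , drop = FALSE] else picked
    }
  }
  if (!is.null(atoms)) out <- out[out$elety %in% atoms, , drop = FALSE]
  new_structure_tbl(out, id = structure_id(structure),
                    source_format = attr(structure, "source_format") %||% "r")
}

#' One-letter sequence of a chain
#'
#' @param structure A `struct_tbl`.
#' @param chain Chain identifier; defaults to the single chain present.
#' @param spans Optional span restriction (string or data frame).
#' @return Character scalar, one letter per polymer residue in author
#'   numbering order (`"X"` for unknown residue names).
#' @export
chain_sequence <- function(structure, chain = NULL, spans = NULL) {
  if (is.null(chain)) {
    chains <- unique(structure$chain)
    if (length(chains) != 1) {
      abort("structure has several chains; pass `chain`")
    }
    chain <- chains
  }
  if (!chain %in% structure$chain) abort(paste0("unknown chain '", chain, "'"))
  s <- structure[structure$chain == chain, , drop = FALSE]
  if (!is.null(spans)) s <- select_region(s, spans)
  paste(residue_table(s)$one_letter, collapse = "")
}

#' Write a structure (or selection) as a minimal PDB file
#'
#' Debug/interchange dump: ATOM records only, author numbering preserved.
#'
#' @param structure A `struct_tbl`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  fmt <- "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  name4 <- ifelse(nchar(structure$elety) >= 4, substr(structure$elety, 1, 4),
                  paste0(" ", formatC(structure$elety, width = -3)))
  lines <- sprintf(fmt, seq_len(nrow(structure)), name4, structure$resname,
                   substr(structure$chain, 1, 1), structure$resno,
                   substr(paste0(structure$insert, " "), 1, 1),
                   structure$x, structure$y, structure$z,
                   structure$occupancy, 0, structure$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Backbone coordinate matrices (N, CA, C, O and H if present) for one chain,
# ordered by author numbering; rows are residues in `rt` order.
backbone_matrices <- function(structure, chain = NULL) {
  if (!is.null(chain)) structure <- structure[structure$chain == chain, , drop = FALSE]
  rt <- residue_table(structure)
  key_s <- paste(structure$chain, structure$resno, structure$insert, sep = "\r")
  key_r <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  get <- function(name) {
    m <- matrix(NA_real_, nrow(rt), 3)
    sel <- structure$elety == name
    idx <- match(key_s[sel], key_r)
    m[idx, ] <- cbind(structure$x[sel], structure$y[sel], structure$z[sel])
    m
  }
  list(residues = rt, N = get("N"), CA = get("CA"), C = get("C"),
       O = get("O"), H = get("H"))
}
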