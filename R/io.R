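# File formats: XYZ geometries (Angstrom), the per-atom charge CSV schema
# (0-based atom_index, element, q_neutral, q_anion, q_cation), FASTA
# receptor sequences, and a lenient parser for population-analysis text
# blocks from quantum-chemistry output. All on-disk atom indices are
# 0-based; in-memory molecule indices are 1-based.

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then one
#' `element x y z` line per atom (coordinates in Angstrom).
#'
#' @param path File path.
#' @return A `molecule` (name taken from the comment line if non-empty).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ file too short: ", path)
  count <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(count) || count < 1L)
    stop("line 1: invalid atom count '", lines[1L], "'")
  if (length(lines) < 2L + count)
    stop("count line says ", count, " atoms but file has only ",
         max(0L, length(lines) - 2L), " atom lines")
  elements <- character(count)
  coords <- matrix(NA_real_, count, 3L)
  for (k in seq_len(count)) {
    ln <- 2L + k
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) stop("line ", ln, ": expected 'element x y z'")
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) stop("line ", ln, ": unparseable coordinate")
    elements[k] <- tok[1L]
    coords[k, ] <- xyz
  }
  tryCatch(covalent_radius(unique(elements)),
           error = function(e) stop("in ", path, ": ", conditionMessage(e)))
  name <- trimws(lines[2L])
  molecule(elements, coords, name = if (nzchar(name)) name else "molecule")
}

#' Write a molecule to an XYZ file
#'
#' @param mol A `molecule`.
#' @param path Output path.
#' @param digits Coordinate decimals (default 6).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, digits = 6L) {
  stopifnot(inherits(mol, "molecule"))
  fmt <- sprintf("%%-3s %%.%df %%.%df %%.%df", digits, digits, digits)
  lines <- c(as.character(n_atoms(mol)), mol$name,
             sprintf(fmt, mol$elements, mol$coords[, 1], mol$coords[, 2],
                     mol$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read neutral/anion/cation charge sets from CSV
#'
#' Schema: columns `atom_index` (0-based), `element`, `q_neutral`,
#' `q_anion`, `q_cation`; one row per atom, any row order. The element
#' column is cross-checked against the molecule and the three column sums
#' must match the state charges 0 / -1 / +1 within 1e-3.
#'
#' @param path CSV path.
#' @param mol The `molecule` the charges belong to.
#' @return List with `charge_set`s `neutral`, `anion`, `cation`.
#' @export
read_charge_csv <- function(path, mol) {
  stopifnot(inherits(mol, "molecule"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("atom_index", "element", "q_neutral", "q_anion", "q_cation")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("charge CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  n <- n_atoms(mol)
  if (nrow(df) != n) stop("charge CSV has ", nrow(df), " rows; molecule has ", n, " atoms")
  idx <- as.integer(df$atom_index)
  if (!setequal(idx, 0:(n - 1L))) stop("atom_index must cover 0..", n - 1L, " exactly")
  df <- df[order(idx), ]
  mism <- which(df$element != mol$elements)
  if (length(mism))
    stop("element mismatch at atom_index ", mism[1L] - 1L, ": CSV has '",
         df$element[mism[1L]], "', molecule has '", mol$elements[mism[1L]], "'")
  list(neutral = charge_set(df$q_neutral, "neutral"),
       anion = charge_set(df$q_anion, "anion"),
       cation = charge_set(df$q_cation, "cation"))
}

#' Write neutral/anion/cation charge sets to CSV
#'
#' @param mol The `molecule`.
#' @param neutral,anion,cation The three `charge_set`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_charge_csv <- function(mol, neutral, anion, cation, path) {
  df <- data.frame(atom_index = seq_len(n_atoms(mol)) - 1L,
                   element = mol$elements,
                   q_neutral = neutral$charges,
                   q_anion = anion$charges,
                   q_cation = cation$charges)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read amino-acid sequences from a FASTA file
#'
#' @param path FASTA path (one or more records).
#' @return Named character vector of uppercase sequences (names from the
#'   record headers), validated against the standard one-letter codes.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(aas))
  names(seqs) <- names(aas)
  for (s in seqs) composition_from_sequence(s)  # residue validation
  seqs
}

#' Lenient parser for a population-analysis text block
#'
#' Best-effort extraction of per-atom partial charges from the
#' population-analysis section of common quantum-chemistry output (lines of
#' the form `"<index> <element> [:] <charge> ..."`, e.g. an ORCA Hirshfeld
#' block). Dialects vary; only the atom index, element and first charge
#' column are used.
#'
#' @param text Character vector of lines, or a file path.
#' @return Data frame with `atom_index` (0-based), `element`, `charge`.
#' @export
parse_population_charges <- function(text) {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text, warn = FALSE)
  pat <- "^\\s*(\\d+)\\s+([A-Z][a-z]?)\\s*:?\\s+(-?\\d+\\.\\d+)"
  m <- regmatches(text, regexec(pat, text))
  hits <- m[vapply(m, length, integer(1)) == 4L]
  if (length(hits) == 0L) stop("no population-analysis lines recognized")
  data.frame(atom_index = as.integer(vapply(hits, `[`, character(1), 2L)),
             element = vapply(hits, `[`, character(1), 3L),
             charge = as.numeric(vapply(hits, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' Write a synthetic fixture bundle to a directory
#'
#' Emits the XYZ geometry, the charge CSV and a dose-response CSV
#' (`compound, dose_um, replicate, response_pct_bapmax`) for one seeded
#' fixture, as the `simulate` CLI subcommand does.
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture_bundle <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- random_drf_fixture(seed)
  xyz <- file.path(dir, sprintf("fixture_%d.xyz", seed))
  chg <- file.path(dir, sprintf("fixture_%d_charges.csv", seed))
  dr <- file.path(dir, sprintf("fixture_%d_doseresponse.csv", seed))
  write_xyz(fx$mol, xyz)
  write_charge_csv(fx$mol, fx$charges$neutral, fx$charges$anion,
                   fx$charges$cation, chg)
  curve <- simulate_dose_response(fx$spec)
  reps <- ave(seq_len(nrow(curve)), curve$dose, FUN = seq_along)
  utils::write.csv(
    data.frame(compound = attr(curve, "compound"), dose_um = curve$dose,
               replicate = reps, response_pct_bapmax = curve$response),
    dr, row.names = FALSE, quote = FALSE)
  invisible(c(xyz = xyz, charges = chg, dose_response = dr))
}
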