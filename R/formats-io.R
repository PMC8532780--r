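#' Structure model container
#'
#' A `structure_model` holds an ordered atom table plus optional
#' crystallographic metadata. Coordinates are Cartesian Angstroms.
#' Residue numbering is 1-based along the chain; index 0 is reserved for an
#' N-terminal acetyl cap.
#'
#' @param atoms data.frame with columns `element`, `name`, `resid`
#'   (3-letter residue code, e.g. `ALA`, `AIB`, `PHL`, `ACE`), `resno`
#'   (integer residue index), `chain`, `x`, `y`, `z`.
#' @param cell optional list with `lengths` (a, b, c in Angstrom) and
#'   `angles` (alpha, beta, gamma in degrees); `NA` entries mark values
#'   missing from the source file.
#' @param space_group optional space-group symbol (e.g. `"P 21"`).
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, cell = NULL, space_group = NULL) {
  required <- c("element", "name", "resid", "resno", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[required]
  atoms$resno <- as.integer(atoms$resno)
  if (!all(is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(atoms$resno < 0))
    stop("residue indices must be >= 0 (0 is reserved for the acetyl cap)")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom key (chain, residue index, atom name): ",
         key[which(duplicated(key))[1]])
  for (ch in unique(atoms$chain)) {
    rn <- sort(unique(atoms$resno[atoms$chain == ch]))
    if (length(rn) > 1 && !all(diff(rn) == 1L))
      stop("residue indices not contiguous in chain ", ch)
  }
  structure(list(atoms = atoms, cell = cell, space_group = space_group),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- length(unique(paste(x$atoms$chain, x$atoms$resno)))
  cat("structure_model:", nrow(x$atoms), "atoms,", nres, "residues\n")
  if (!is.null(x$cell))
    cat("  cell:", paste(signif(unlist(x$cell), 6), collapse = " "), "\n")
  if (!is.null(x$space_group))
    cat("  space group:", x$space_group, "\n")
  invisible(x)
}

# Fetch coordinates of one atom; NULL if absent.
atom_coords <- function(model, resno, name, chain = NULL) {
  a <- model$atoms
  sel <- a$resno == resno & a$name == name
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) return(NULL)
  as.numeric(a[which(sel)[1], c("x", "y", "z")])
}

#' Read a peptide structure from PDB or mmCIF
#'
#' PDB files are parsed with \pkg{bio3d}; only the first model of a
#' multi-model file is kept and insertion codes are rejected. mmCIF files
#' are read with a bundled reader that accepts both Cartesian
#' (`_atom_site.Cartn_x`) and fractional (`_atom_site.fract_x`)
#' coordinates; fractional coordinates are converted to Cartesian using the
#' cell. Nonstandard residue names (AIB, PHL, ACE) are preserved verbatim.
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"mmcif"` (default guessed from extension).
#' @return a [structure_model].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (dialect == "pdb") read_structure_pdb(path) else read_structure_mmcif(path)
}

read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad) > 0)
    stop("malformed ATOM/HETATM record at line ", bad[1], " of ", path)
  coords_txt <- substring(lines[is_atom], 31, 54)
  if (any(is.na(suppressWarnings(as.numeric(c(
        substring(coords_txt, 1, 8), substring(coords_txt, 9, 16),
        substring(coords_txt, 17, 24)))))))
    stop("non-numeric coordinates in ATOM/HETATM record of ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported: ", path)
  known <- c(aa3_codes(), "AIB", "PHL", "ACE")
  unknown <- setdiff(unique(at$resid), known)
  if (length(unknown) > 0)
    warning("unknown residue name(s) retained: ",
            paste(unknown, collapse = ", "))
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)))
    elem <- substring(gsub("[0-9]", "", at$elety), 1, 1)
  elem[is.na(elem) | elem == ""] <-
    substring(gsub("[0-9]", "", at$elety[is.na(elem) | elem == ""]), 1, 1)
  cell <- parse_cryst1(lines)
  structure_model(
    data.frame(element = elem, name = at$elety, resid = at$resid,
               resno = at$resno, chain = chain,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    cell = cell$cell, space_group = cell$space_group)
}

parse_cryst1 <- function(lines) {
  cl <- lines[grepl("^CRYST1", lines)]
  if (length(cl) == 0) return(list(cell = NULL, space_group = NULL))
  cl <- cl[1]
  num <- function(i, j) suppressWarnings(as.numeric(substring(cl, i, j)))
  cell <- list(lengths = c(num(7, 15), num(16, 24), num(25, 33)),
               angles = c(num(34, 40), num(41, 47), num(48, 54)))
  sg <- trimws(substring(cl, 56, 66))
  list(cell = cell, space_group = if (nzchar(sg)) sg else NULL)
}

# --- minimal CIF machinery ------------------------------------------------
# bio3d's CIF reader does not expose the unit cell and requires Cartesian
# coordinates, so mmCIF is handled by this small reader/writer pair.

cif_tokenize <- function(line) {
  # split on whitespace, honouring single/double quotes
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

read_structure_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  cell_tags <- c(a = "_cell.length_a", b = "_cell.length_b",
                 c = "_cell.length_c", alpha = "_cell.angle_alpha",
                 beta = "_cell.angle_beta", gamma = "_cell.angle_gamma")
  cif_value <- function(tag) {
    hit <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    # legacy core-CIF spelling (_cell_length_a)
    if (length(hit) == 0) {
      alt <- sub("\\.", "_", tag)
      hit <- grep(paste0("^", alt, "[[:space:]]"), lines, value = TRUE)
    }
    if (length(hit) == 0) return(NA_real_)
    val <- cif_tokenize(hit[1])[2]
    if (val %in% c("?", ".")) return(NA_real_)
    suppressWarnings(as.numeric(sub("\\(.*\\)", "", val)))
  }
  cellv <- vapply(cell_tags, cif_value, numeric(1))
  cell <- NULL
  if (any(!is.na(cellv)))
    cell <- list(lengths = unname(cellv[1:3]), angles = unname(cellv[4:6]))
  sg_hit <- grep("^_(symmetry\\.space_group_name_H-M|symmetry_space_group_name_H-M|space_group\\.name_H-M_alt)[[:space:]]",
                 lines, value = TRUE)
  space_group <- if (length(sg_hit) > 0) cif_tokenize(sg_hit[1])[2] else NULL

  # locate the atom_site loop
  loop_idx <- grep("^\\s*loop_\\s*$", lines)
  atoms <- NULL
  for (li in loop_idx) {
    j <- li + 1
    tags <- character(0)
    while (j <= length(lines) && grepl("^_", trimws(lines[j]))) {
      tags <- c(tags, trimws(cif_tokenize(lines[j])[1]))
      j <- j + 1
    }
    if (!any(grepl("^_atom_site\\.", tags))) next
    rows <- list()
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (ln == "" || grepl("^(loop_|_|data_)", ln)) break
      toks <- cif_tokenize(ln)
      if (length(toks) != length(tags))
        stop("atom_site row at line ", j, " has ", length(toks),
             " fields, expected ", length(tags))
      rows[[length(rows) + 1]] <- toks
      j <- j + 1
    }
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- tags
    atoms <- tab
    break
  }
  if (is.null(atoms)) stop("no _atom_site loop found in ", path)

  g <- function(tag, alt = NULL) {
    for (t in c(tag, alt)) if (!is.null(t) && t %in% names(atoms))
      return(atoms[[t]])
    NULL
  }
  num <- function(v) {
    if (is.null(v)) return(NULL)
    suppressWarnings(as.numeric(ifelse(v %in% c("?", "."), NA, v)))
  }
  ins <- g("_atom_site.pdbx_PDB_ins_code")
  if (!is.null(ins) && any(!ins %in% c("?", ".", "")))
    stop("insertion codes are not supported: ", path)
  x <- num(g("_atom_site.Cartn_x"))
  if (is.null(x)) {
    fx <- num(g("_atom_site.fract_x"))
    fy <- num(g("_atom_site.fract_y"))
    fz <- num(g("_atom_site.fract_z"))
    if (is.null(fx)) stop("atom_site loop has neither Cartn nor fract coordinates")
    if (is.null(cell) || any(is.na(unlist(cell))))
      stop("fractional coordinates require a complete unit cell")
    M <- fractional_matrix(cell)
    xyz <- t(M %*% rbind(fx, fy, fz))
    x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  } else {
    y <- num(g("_atom_site.Cartn_y"))
    z <- num(g("_atom_site.Cartn_z"))
  }
  name <- g("_atom_site.auth_atom_id", "_atom_site.label_atom_id")
  resid <- g("_atom_site.auth_comp_id", "_atom_site.label_comp_id")
  resno <- num(g("_atom_site.auth_seq_id", "_atom_site.label_seq_id"))
  chain <- g("_atom_site.auth_asym_id", "_atom_site.label_asym_id")
  if (is.null(chain)) chain <- "A"
  elem <- g("_atom_site.type_symbol")
  if (is.null(elem)) elem <- substring(gsub("[0-9]", "", name), 1, 1)
  known <- c(aa3_codes(), "AIB", "PHL", "ACE")
  unknown <- setdiff(unique(resid), known)
  if (length(unknown) > 0)
    warning("unknown residue name(s) retained: ",
            paste(unknown, collapse = ", "))
  structure_model(
    data.frame(element = elem, name = name, resid = resid,
               resno = as.integer(resno), chain = chain, x = x, y = y, z = z,
               stringsAsFactors = FALSE),
    cell = cell, space_group = space_group)
}

# Cartesian <- M %*% fractional for a triclinic cell.
fractional_matrix <- function(cell) {
  l <- cell$lengths; ang <- deg2rad(cell$angles)
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3]); sg <- sin(ang[3])
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  matrix(c(l[1], l[2] * cg, l[3] * cb,
           0,    l[2] * sg, l[3] * (ca - cb * cg) / sg,
           0,    0,         l[3] * v / sg),
         3, 3, byrow = TRUE)
}

#' Write a structure model to PDB or mmCIF
#'
#' `read_structure(write_structure(m))` reproduces `m` exactly for mmCIF
#' and to 3 decimal places (the format's precision) for PDB.
#'
#' @param model a [structure_model].
#' @param path output file path.
#' @param dialect `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!inherits(model, "structure_model")) stop("model must be a structure_model")
  if (dialect == "pdb") write_structure_pdb(model, path)
  else write_structure_mmcif(model, path)
  invisible(path)
}

write_structure_pdb <- function(model, path) {
  a <- model$atoms
  lines <- character(0)
  if (!is.null(model$cell)) {
    sg <- if (is.null(model$space_group)) "P 1" else model$space_group
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11sZ", model$cell$lengths[1],
      model$cell$lengths[2], model$cell$lengths[3], model$cell$angles[1],
      model$cell$angles[2], model$cell$angles[3], sg))
  }
  if (nrow(a) > 0) {
    standard <- a$resid %in% aa3_codes()
    rectype <- ifelse(standard, "ATOM  ", "HETATM")
    atname <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                     sprintf("%-4s", a$name))
    lines <- c(lines, sprintf(
      "%s%5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, seq_len(nrow(a)), atname, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, 1, 0, a$element))
  }
  writeLines(c(lines, "END"), path)
}

write_structure_mmcif <- function(model, path) {
  a <- model$atoms
  lines <- c("data_model")
  if (!is.null(model$cell)) {
    fmt <- function(v) ifelse(is.na(v), "?", sprintf("%.4f", v))
    lines <- c(lines,
      paste("_cell.length_a", fmt(model$cell$lengths[1])),
      paste("_cell.length_b", fmt(model$cell$lengths[2])),
      paste("_cell.length_c", fmt(model$cell$lengths[3])),
      paste("_cell.angle_alpha", fmt(model$cell$angles[1])),
      paste("_cell.angle_beta", fmt(model$cell$angles[2])),
      paste("_cell.angle_gamma", fmt(model$cell$angles[3])))
  }
  if (!is.null(model$space_group))
    lines <- c(lines, paste0("_symmetry.space_group_name_H-M '",
                             model$space_group, "'"))
  lines <- c(lines, "loop_",
             "_atom_site.group_PDB", "_atom_site.id",
             "_atom_site.type_symbol", "_atom_site.auth_atom_id",
             "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
             "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
             "_atom_site.Cartn_y", "_atom_site.Cartn_z")
  if (nrow(a) > 0) {
    standard <- a$resid %in% aa3_codes()
    lines <- c(lines, sprintf("%s %d %s %s %s %s %d %.17g %.17g %.17g",
      ifelse(standard, "ATOM", "HETATM"), seq_len(nrow(a)), a$element,
      a$name, a$resid, a$chain, a$resno, a$x, a$y, a$z))
  }
  writeLines(lines, path)
}

aa3_codes <- function() c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

# --- MAGRES ----------------------------------------------------------------

#' Read magnetic-shielding tensors from a MAGRES file
#'
#' Parses the `[atoms]` and `[magres]` blocks of a magres-file-format v1.0
#' file and returns one tensor record per `ms` line. Atom labels are
#' matched to residues by (label, index): the label is the atom name and
#' the index is the residue index, the convention used by
#' [write_magres()]. Shieldings are reported in ppm.
#'
#' @param path MAGRES file path.
#' @param model optional [structure_model]; when supplied, every record
#'   must resolve to exactly one atom site or an error is raised.
#' @param chain chain identifier used when resolving sites (single-chain
#'   convention).
#' @return a list of records, each with `site_key` (list: chain, resno,
#'   name) and `matrix` (3x3 shielding tensor, ppm).
#' @export
read_magres <- function(path, model = NULL, chain = "A") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  in_atoms <- FALSE; in_magres <- FALSE
  atoms_seen <- character(0)
  records <- list()
  closed_magres <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (ln == "[atoms]") { in_atoms <- TRUE; next }
    if (ln == "[/atoms]") { in_atoms <- FALSE; next }
    if (ln == "[magres]") { in_magres <- TRUE; next }
    if (ln == "[/magres]") { in_magres <- FALSE; closed_magres <- TRUE; next }
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    if (in_atoms && toks[1] == "atom") {
      if (length(toks) < 7)
        stop("malformed atom line at line ", i, " of ", path)
      atoms_seen <- c(atoms_seen, paste(toks[3], toks[4]))
    }
    if (in_magres && toks[1] == "units") {
      if (toks[2] == "ms" && toks[3] != "ppm")
        stop("unsupported ms units '", toks[3], "' (expected ppm)")
      next
    }
    if (in_magres && toks[1] == "ms") {
      if (length(toks) != 12)
        stop("ms line at line ", i, " of ", path,
             " does not carry a 3x3 tensor (", length(toks) - 3, " values)")
      vals <- suppressWarnings(as.numeric(toks[4:12]))
      if (any(is.na(vals)))
        stop("non-numeric tensor entry at line ", i, " of ", path)
      label <- toks[2]; index <- as.integer(toks[3])
      if (length(atoms_seen) > 0 &&
          !(paste(label, index) %in% atoms_seen))
        stop("ms line at line ", i, " references unknown atom ",
             label, " ", index)
      records[[length(records) + 1]] <- list(
        site_key = list(chain = chain, resno = index, name = label),
        matrix = matrix(vals, 3, 3, byrow = TRUE))
    }
  }
  if (in_atoms || in_magres || (!closed_magres && length(records) > 0))
    stop("truncated MAGRES file (unterminated block) at line ",
         length(lines), " of ", path)
  if (!is.null(model)) {
    for (r in records) {
      if (is.null(atom_coords(model, r$site_key$resno, r$site_key$name,
                              r$site_key$chain)))
        stop("tensor record for ", r$site_key$name, " ", r$site_key$resno,
             " has no matching atom site in the model")
    }
  }
  records
}

#' Write shielding tensors to a MAGRES file
#'
#' Companion writer to [read_magres()]; emits magres-file-format v1.0 with
#' atom label = atom name and index = residue index.
#'
#' @param records list of tensor records (`site_key`, `matrix`).
#' @param model the [structure_model] the records refer to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_magres <- function(records, model, path) {
  lines <- c("#$magres-abinitio-v1.0", "[atoms]", "units atom Angstrom")
  a <- model$atoms
  for (i in seq_len(nrow(a)))
    lines <- c(lines, sprintf("atom %s %s %d %.6f %.6f %.6f",
      a$element[i], a$name[i], a$resno[i], a$x[i], a$y[i], a$z[i]))
  lines <- c(lines, "[/atoms]", "[magres]", "units ms ppm")
  for (r in records)
    lines <- c(lines, paste("ms", r$site_key$name, r$site_key$resno,
      paste(sprintf("%.8f", as.vector(t(r$matrix))), collapse = " ")))
  lines <- c(lines, "[/magres]")
  writeLines(lines, path)
  invisible(path)
}
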