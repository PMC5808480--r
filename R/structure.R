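# Atomic structure model: a light S3 container over an atom table, backed by
# bio3d for PDB parsing and Kabsch superposition.

METAL_ELEMENTS <- c("CU", "ZN", "FE", "MN", "CO", "NI", "MG", "CA", "NA", "K")

#' Construct a structure from an atom table
#'
#' The atom table is the unit all geometry in the package operates on.
#' Coordinates are in Angstrom throughout; no unit conversion happens
#' anywhere downstream.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `insert`, `chain`, `x`, `y`, `z`. Flag columns
#'   `is_hydrogen`/`is_metal` are derived from `element` if absent.
#' @param id structure identifier string.
#' @return An object of class `enstab_structure`: a list with `id`,
#'   `atoms` (the validated table) and `chains` (chain ids in order of
#'   first appearance).
#' @export
as_structure <- function(atoms, id = "structure") {
  needed <- c("serial", "name", "element", "resname", "resno", "chain",
              "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in atom table")
  }
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$element <- toupper(trimws(atoms$element))
  if (is.null(atoms$is_hydrogen)) {
    atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  }
  if (is.null(atoms$is_metal)) {
    # CA/NA/K are also element symbols of common protein atoms or ions
    # written without HETATM context: only unambiguous transition-metal
    # symbols are flagged unless the record type marks a heteroatom
    unambiguous <- c("CU", "ZN", "FE", "MN", "CO", "NI", "MG")
    atoms$is_metal <- if (!is.null(atoms$hetatm)) {
      atoms$hetatm & atoms$element %in% METAL_ELEMENTS
    } else {
      atoms$element %in% unambiguous
    }
  }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom name) keys: ",
         paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
  }
  # every residue needs at least one heavy atom
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert)
  heavy <- tapply(!atoms$is_hydrogen, rkey, any)
  if (!all(heavy)) {
    stop("residues without heavy atoms: ",
         paste(names(heavy)[!heavy], collapse = ", "))
  }
  rownames(atoms) <- NULL
  structure(
    list(id = id, atoms = atoms, chains = unique(atoms$chain)),
    class = "enstab_structure"
  )
}

#' @export
print.enstab_structure <- function(x, ...) {
  cat(sprintf(
    "<enstab_structure> %s: %d atoms, chains %s, %d residues\n",
    x$id, nrow(x$atoms), paste(x$chains, collapse = ","),
    length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert)))
  ))
  invisible(x)
}

#' Coordinates of a structure as an N x 3 matrix
#' @param structure an `enstab_structure`.
#' @return numeric matrix with one row per atom (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace coordinates of a structure
#' @param structure an `enstab_structure`.
#' @param xyz N x 3 matrix matching the atom table.
#' @return a structure with updated coordinates.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3L)
  structure$atoms$x <- xyz[, 1L]
  structure$atoms$y <- xyz[, 2L]
  structure$atoms$z <- xyz[, 3L]
  structure
}

#' Extract one chain as a structure
#' @param structure an `enstab_structure`.
#' @param chain chain identifier.
#' @return an `enstab_structure` restricted to `chain`.
#' @export
chain_structure <- function(structure, chain) {
  keep <- structure$atoms$chain == chain
  if (!any(keep)) stop("no atoms in chain ", chain)
  as_structure(structure$atoms[keep, , drop = FALSE],
               id = paste0(structure$id, ":", chain))
}

#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records via bio3d. Alternate locations
#' are resolved by keeping the highest-occupancy conformer of each atom;
#' insertion codes are preserved as part of the residue key. Metal ions
#' (Cu, Zn, ...) are flagged `is_metal`, hydrogens `is_hydrogen`.
#'
#' @param path PDB file path.
#' @param model_index 1-based model to extract from multi-model files.
#' @return an `enstab_structure`.
#' @export
read_pdb <- function(path, model_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  # validate coordinate fields up-front so we can name the offending line
  for (i in which(rec)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields)))) {
      stop("malformed coordinate field at line ", i, " of ", path)
    }
  }
  multi <- any(grepl("^MODEL", lines))
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  xyz <- if (multi) {
    if (model_index > nrow(pdb$xyz)) {
      stop("model ", model_index, " not present (", nrow(pdb$xyz), " models)")
    }
    matrix(pdb$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  } else {
    matrix(pdb$xyz[1L, ], ncol = 3L, byrow = TRUE)
  }
  occ <- ifelse(is.na(at$o), 1, at$o)
  element <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                   substr(trimws(at$elety), 1L, 1L),
                                   at$elesy)))
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = element,
    resname = trimws(at$resid),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    hetatm = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  # altloc: keep the highest-occupancy record per (chain, resno, insert, name)
  akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(akey)) {
    ord <- order(akey, -occ, atoms$serial)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$name)), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("empty model in ", path)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  atoms$is_metal <- atoms$hetatm & atoms$element %in% METAL_ELEMENTS
  as_structure(atoms, id = sub("\\.pdb$", "", basename(path)))
}

#' Write a structure to a PDB file
#'
#' Standard fixed-column output with TER records between chains;
#' coordinates are written with 3 decimals, so read/write round-trips
#' reproduce coordinates to 0.001 Angstrom.
#'
#' @param structure an `enstab_structure`.
#' @param path output path.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  if (nrow(at) == 0L) stop("refusing to write empty structure")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  n <- nrow(at)
  for (i in seq_len(n)) {
    serial <- serial + 1L
    rec <- if (isTRUE(at$hetatm[i])) "HETATM" else "ATOM  "
    name <- at$name[i]
    # column convention: 1-char element names start in column 14
    name_fmt <- if (nchar(name) < 4L && nchar(at$element[i]) == 1L) {
      sprintf(" %-3s", name)
    } else {
      sprintf("%-4s", name)
    }
    writeLines(sprintf(
      "%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, serial, name_fmt, at$resname[i], at$chain[i], at$resno[i],
      ifelse(at$insert[i] == "", " ", at$insert[i]),
      at$x[i], at$y[i], at$z[i], 1, 0, at$element[i]
    ), con)
    # atoms are written in stored order; close each contiguous chain
    # block with a TER record
    if (i == n || at$chain[i + 1L] != at$chain[i]) {
      serial <- serial + 1L
      writeLines(sprintf("TER   %5d      %-3s %1s%4d",
                         serial, at$resname[i], at$chain[i],
                         at$resno[i]), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Superpose two structures and report the RMSD
#'
#' Atoms are paired by `(resno, insert, name)` (chain-agnostic, so two
#' chains of a homodimer can be compared); unpaired atoms are dropped
#' with a message. The mobile copy is fitted onto the fixed one by
#' least-squares rigid superposition (Kabsch, via bio3d) and the
#' root-mean-square deviation over all paired atoms is returned.
#'
#' @param a,b structures to compare (`a` fixed, `b` mobile).
#' @param heavy_only drop hydrogens before pairing (default FALSE:
#'   all atomic pairs).
#' @return RMSD in Angstrom (scalar), with attribute `n_pairs`.
#' @export
superpose_rmsd <- function(a, b, heavy_only = FALSE) {
  ta <- a$atoms
  tb <- b$atoms
  if (heavy_only) {
    ta <- ta[!ta$is_hydrogen, , drop = FALSE]
    tb <- tb[!tb$is_hydrogen, , drop = FALSE]
  }
  ka <- paste(ta$resno, ta$insert, ta$name)
  kb <- paste(tb$resno, tb$insert, tb$name)
  common <- intersect(ka, kb)
  dropped <- (nrow(ta) - length(common)) + (nrow(tb) - length(common))
  if (dropped > 0L) {
    message(dropped, " unpaired atoms dropped from superposition")
  }
  if (length(common) < 3L) {
    stop("degenerate pairing: only ", length(common), " atom pairs")
  }
  xa <- as.matrix(ta[match(common, ka), c("x", "y", "z")])
  xb <- as.matrix(tb[match(common, kb), c("x", "y", "z")])
  inds <- seq_len(3L * length(common))
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(xa)),
                           mobile = as.numeric(t(xb)),
                           fixed.inds = inds, mobile.inds = inds)
  d2 <- rowSums((xa - matrix(fitted, ncol = 3L, byrow = TRUE))^2)
  out <- sqrt(mean(d2))
  attr(out, "n_pairs") <- length(common)
  out
}

#' Residue annotations for the SOD1 dimer
#'
#' Functional and structural position sets for superoxide dismutase-1
#' (153 residues per subunit), applicable to both chains: metal-binding
#' sites, the four structurally important loops, the disulfide bridge,
#' the dimer interface, and residues reported in contact between
#' aggregates.
#'
#' @return named list of integer position vectors (1..153 per chain).
#' @export
sod1_residue_annotations <- function() {
  list(
    zinc_site = c(63L, 71L, 80L, 83L),
    copper_site = c(46L, 48L, 63L, 120L),
    disulfide = c(57L, 146L),
    loop_disulfide = 49:62,
    loop_zinc = 63:85,
    loop_greek_key = 102:115,
    loop_electrostatic = 121:142,
    dimer_interface = c(5L, 7L, 17L, 50:54, 113:115, 148L, 150:153),
    aggregate_contact = c(11:15, 24L, 26L, 91:92, 97:99, 101:104, 109L,
                          128:131)
  )
}

#' Positions important for SOD1 structure
#'
#' The 25 positions used as the reference set for per-position mean
#' stiffness: metal-binding residues, the dimer interface, and the
#' disulfide-bond cysteines.
#'
#' @return sorted integer vector of 25 positions.
#' @export
sod1_important_positions <- function() {
  ann <- sod1_residue_annotations()
  sort(unique(c(ann$zinc_site, ann$copper_site, ann$dimer_interface,
                ann$disulfide)))
}
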