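# Atomic numbers for the elements that occur in SYBYL-typed small molecules.
.ELEMENT_Z <- c(
  H = 1L, Li = 3L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L,
  Mg = 12L, Al = 13L, Si = 14L, P = 15L, S = 16L, Cl = 17L, K = 19L,
  Ca = 20L, Cr = 24L, Mn = 25L, Fe = 26L, Co = 27L, Cu = 29L, Zn = 30L,
  Se = 34L, Br = 35L, Mo = 42L, Sn = 50L, I = 53L
)

.BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Construct a molecule
#'
#' A molecule is the atom/bond graph this package works on: an ordered atom
#' table (1-based contiguous indices, element symbols, optional SYBYL types
#' and coordinates) plus a bond list.  Most users will not call this directly
#' but obtain molecules from [read_molecule()] or the fixture generator.
#'
#' @param compound_id Character scalar naming the compound.
#' @param atoms Data frame with columns `index`, `element`, and optionally
#'   `sybyl_type`, `x`, `y`, `z`.  `atomic_number` is filled from `element`.
#' @param bonds Data frame with columns `a`, `b` (atom indices) and `order`
#'   (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`).
#' @return An object of class `molecule`.
#' @export
molecule <- function(compound_id, atoms, bonds) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop("molecule must have at least one atom")
  atoms$index <- as.integer(atoms$index)
  if (!identical(atoms$index, seq_len(nrow(atoms))))
    stop("atom indices must be contiguous from 1")
  if (is.null(atoms$sybyl_type)) atoms$sybyl_type <- NA_character_
  if (is.null(atoms$atomic_number))
    atoms$atomic_number <- unname(.ELEMENT_Z[atoms$element])
  for (col in c("x", "y", "z")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  if (nrow(bonds) > 0L) {
    bonds$a <- as.integer(bonds$a)
    bonds$b <- as.integer(bonds$b)
    if (any(bonds$a < 1L | bonds$a > nrow(atoms) |
            bonds$b < 1L | bonds$b > nrow(atoms)))
      stop("bond references a non-existent atom")
    if (!all(bonds$order %in% .BOND_ORDERS))
      stop("bond order must be one of: ", paste(.BOND_ORDERS, collapse = ", "))
  } else {
    bonds <- data.frame(a = integer(), b = integer(), order = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(compound_id = as.character(compound_id),
                 atoms = atoms[, c("index", "element", "atomic_number",
                                   "sybyl_type", "x", "y", "z")],
                 bonds = bonds[, c("a", "b", "order")]),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$compound_id, ": ", nrow(x$atoms), " atoms (",
      sum(x$atoms$element != "H"), " heavy), ", nrow(x$bonds), " bonds\n",
      sep = "")
  invisible(x)
}

#' Indices of the heavy (non-hydrogen) atoms of a molecule
#' @param mol A [molecule()].
#' @return Integer vector of atom indices.
#' @export
heavy_atoms <- function(mol) {
  mol$atoms$index[mol$atoms$element != "H"]
}

# ---- MOL2 parsing / writing --------------------------------------------

# Open Babel writes "S.O2"/"S.O"; Tripos convention is lower case.
.normalize_sybyl <- function(codes) {
  codes[codes == "S.O2"] <- "S.o2"
  codes[codes == "S.O"] <- "S.o"
  codes
}

.mol2_bond_order <- c("1" = "single", "2" = "double", "3" = "triple",
                      "ar" = "aromatic", "am" = "single", "du" = "single",
                      "un" = "single", "nc" = "single")

.element_from_sybyl <- function(type, name) {
  el <- sub("\\..*$", "", type)
  el[!(el %in% names(.ELEMENT_Z))] <- NA_character_
  # fall back on the atom-name column stripped of digits
  miss <- is.na(el)
  if (any(miss)) {
    guess <- sub("[0-9'\"]*$", "", name[miss])
    guess[!(guess %in% names(.ELEMENT_Z))] <- NA_character_
    el[miss] <- guess
  }
  el
}

# Parse the text of one or more Tripos MOL2 records into molecule objects.
parse_mol2 <- function(text, compound_id = NULL) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  starts <- grep("@<TRIPOS>MOLECULE", lines, fixed = TRUE)
  if (length(starts) == 0L)
    stop("MOL2 parse error: no @<TRIPOS>MOLECULE record found")
  ends <- c(starts[-1L] - 1L, length(lines))
  mols <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    name <- trimws(rec[2L])
    atom0 <- grep("@<TRIPOS>ATOM", rec, fixed = TRUE)
    if (length(atom0) != 1L)
      stop("MOL2 parse error in record ", k, ": missing ATOM section")
    sect <- grep("^@<TRIPOS>", rec)
    nxt <- function(i) {
      after <- sect[sect > i]
      if (length(after)) min(after) - 1L else length(rec)
    }
    atom_lines <- rec[(atom0 + 1L):nxt(atom0)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    if (length(atom_lines) == 0L)
      stop("MOL2 parse error in record ", k, ": empty ATOM section")
    f <- strsplit(trimws(atom_lines), "[[:space:]]+")
    nf <- vapply(f, length, 0L)
    if (any(nf < 6L))
      stop("MOL2 parse error in record ", k, ": malformed atom line ",
           which(nf < 6L)[1L])
    typ <- .normalize_sybyl(vapply(f, `[`, "", 6L))
    nm <- vapply(f, `[`, "", 2L)
    atoms <- data.frame(
      index = seq_along(f),
      element = .element_from_sybyl(typ, nm),
      sybyl_type = typ,
      x = as.numeric(vapply(f, `[`, "", 3L)),
      y = as.numeric(vapply(f, `[`, "", 4L)),
      z = as.numeric(vapply(f, `[`, "", 5L)),
      stringsAsFactors = FALSE)
    bond0 <- grep("@<TRIPOS>BOND", rec, fixed = TRUE)
    if (length(bond0) == 1L && nxt(bond0) > bond0) {
      bl <- rec[(bond0 + 1L):nxt(bond0)]
      bl <- bl[nzchar(trimws(bl))]
      bf <- strsplit(trimws(bl), "[[:space:]]+")
      ord <- vapply(bf, `[`, "", 4L)
      bad <- !(ord %in% names(.mol2_bond_order))
      if (any(bad))
        stop("MOL2 parse error in record ", k, ": unknown bond type '",
             ord[bad][1L], "'")
      bonds <- data.frame(a = as.integer(vapply(bf, `[`, "", 2L)),
                          b = as.integer(vapply(bf, `[`, "", 3L)),
                          order = unname(.mol2_bond_order[ord]),
                          stringsAsFactors = FALSE)
    } else {
      bonds <- data.frame(a = integer(), b = integer(), order = character())
    }
    id <- if (!is.null(compound_id)) {
      if (length(compound_id) >= k) compound_id[k] else paste0("mol", k)
    } else if (nzchar(name) && !grepl("^\\*+$", name)) name else paste0("mol", k)
    mols[[k]] <- molecule(id, atoms, bonds)
  }
  mols
}

.looks_like_path <- function(source) {
  length(source) == 1L && !grepl("\n", source, fixed = TRUE) &&
    file.exists(source)
}

.read_source <- function(source) {
  if (.looks_like_path(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
}

#' Read molecules from SMILES, SDF or MOL2
#'
#' SMILES and SDF input is converted to MOL2 with Open Babel (which also
#' assigns SYBYL atom types and perceives aromaticity); MOL2 input is parsed
#' directly and keeps its native types.  Hydrogens explicit in the source are
#' recorded but are excluded from candidate enumeration, topological
#' distances and fingerprints; implicit hydrogens stay implicit.
#'
#' @param source Path to a file, or the raw text itself (SMILES strings may be
#'   given one per line with an optional whitespace-separated compound id).
#' @param format One of `"smiles"`, `"sdf"`, `"mol2"`.
#' @param compound_id Optional character vector of ids overriding names found
#'   in the source.
#' @return `read_molecules()` returns a list of [molecule()] objects;
#'   `read_molecule()` returns the first (and errors if the source is empty).
#' @export
read_molecules <- function(source, format = c("smiles", "sdf", "mol2"),
                           compound_id = NULL) {
  format <- match.arg(format)
  text <- .read_source(source)
  if (!nzchar(trimws(text))) stop("empty ", format, " source")
  if (format == "mol2") return(parse_mol2(text, compound_id))
  from <- c(smiles = "SMI", sdf = "SDF")[[format]]
  if (format == "smiles") {
    sl <- strsplit(text, "\n", fixed = TRUE)[[1]]
    sl <- sl[nzchar(trimws(sl))]
    ids <- vapply(strsplit(trimws(sl), "[[:space:]]+"), function(p) {
      if (length(p) > 1L) p[2L] else NA_character_
    }, "")
    if (is.null(compound_id) && any(!is.na(ids)))
      compound_id <- ifelse(is.na(ids), paste0("mol", seq_along(ids)), ids)
    text <- paste(sl, collapse = "\n")
  }
  mol2 <- tryCatch(
    ChemmineOB::convertFormat(from, "MOL2", source = paste0(text, "\n")),
    error = function(e) stop(format, " parse error: ", conditionMessage(e)))
  if (!nzchar(trimws(mol2)))
    stop(format, " parse error: Open Babel produced no output; ",
         "check the input records")
  parse_mol2(mol2, compound_id)
}

#' @rdname read_molecules
#' @export
read_molecule <- function(source, format = c("smiles", "sdf", "mol2"),
                          compound_id = NULL) {
  mols <- read_molecules(source, format, compound_id)
  mols[[1L]]
}

# Minimal V2000 SDF writer used to hand a bare graph to Open Babel for typing.
.sdf_text <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  coords <- cbind(ifelse(is.na(a$x), 0, a$x), ifelse(is.na(a$y), 0, a$y),
                  ifelse(is.na(a$z), 0, a$z))
  ord <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  header <- c(mol$compound_id, "  fmosom", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      nrow(a), nrow(b)))
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        coords[, 1], coords[, 2], coords[, 3], a$element)
  bond_lines <- if (nrow(b)) {
    sprintf("%3d%3d%3d  0  0  0  0", b$a, b$b, ord[b$order])
  } else character()
  paste(c(header, atom_lines, bond_lines, "M  END", "$$$$", ""),
        collapse = "\n")
}

#' Assign SYBYL atom types to a molecule
#'
#' Untyped molecules are round-tripped through Open Babel (graph out as SDF,
#' back in as MOL2) so that its perception rules provide the types; molecules
#' that already carry a full set of types are returned unchanged unless
#' `override = TRUE`.  Any type Open Babel emits that is not in the configured
#' type table falls back to a generic per-element code (`C.3`-style) with a
#' warning.
#'
#' @param mol A [molecule()].
#' @param override Re-type even if types are already present.
#' @param table A [sybyl_type_table()] used to validate the assignment.
#' @return The molecule with every atom's `sybyl_type` set.
#' @export
assign_sybyl_types <- function(mol, override = FALSE,
                               table = sybyl_type_table()) {
  typed <- !is.na(mol$atoms$sybyl_type) & nzchar(mol$atoms$sybyl_type)
  if (all(typed) && !override) return(mol)
  if (nrow(mol$bonds) == 0L && nrow(mol$atoms) > 1L)
    stop("cannot type a multi-atom molecule without a bond graph")
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "MOL2", source = .sdf_text(mol)),
    error = function(e) NULL)
  new_types <- if (!is.null(out) && nzchar(trimws(out))) {
    parsed <- parse_mol2(out)[[1L]]
    if (nrow(parsed$atoms) != nrow(mol$atoms))
      stop("atom count changed during typing round trip")
    parsed$atoms$sybyl_type
  } else {
    rep(NA_character_, nrow(mol$atoms))
  }
  unknown <- is.na(new_types) | !(new_types %in% table$code)
  if (any(unknown)) {
    el <- mol$atoms$element[unknown]
    fb <- ifelse(el %in% c("C", "N", "O", "S", "P"), paste0(el, ".3"), el)
    fb[!(fb %in% table$code)] <- table$code[1L]
    warning("no typing rule matched ", sum(unknown),
            " atom(s); falling back to generic element type(s): ",
            paste(unique(fb), collapse = ", "))
    new_types[unknown] <- fb
  }
  mol$atoms$sybyl_type <- new_types
  attr(mol, "aromatic_model") <- "openbabel"
  mol
}

#' Write a molecule as Tripos MOL2
#'
#' @param mol A typed [molecule()].
#' @param path Output file; if `NULL` the MOL2 text is returned.
#' @return The MOL2 text, invisibly when written to a file.
#' @export
write_mol2 <- function(mol, path = NULL) {
  a <- mol$atoms
  typ <- ifelse(is.na(a$sybyl_type), a$element, a$sybyl_type)
  ord <- c(single = "1", double = "2", triple = "3", aromatic = "ar")
  b <- mol$bonds
  txt <- paste(c(
    "@<TRIPOS>MOLECULE",
    mol$compound_id,
    sprintf(" %d %d 0 0 0", nrow(a), nrow(b)),
    "SMALL", "NO_CHARGES", "",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-4s %10.4f %10.4f %10.4f %-7s %d %-8s %10.4f",
            a$index, paste0(a$element, a$index),
            ifelse(is.na(a$x), 0, a$x), ifelse(is.na(a$y), 0, a$y),
            ifelse(is.na(a$z), 0, a$z), typ, 1L, "UNL1", 0),
    "@<TRIPOS>BOND",
    if (nrow(b)) sprintf("%6d %5d %5d %4s", seq_len(nrow(b)), b$a, b$b,
                         ord[b$order]) else character(),
    ""), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Topological distances from a center atom
#'
#' Breadth-first shortest bond-path lengths over the heavy-atom graph
#' (hydrogens and bonds to hydrogens are ignored).
#'
#' @param mol A [molecule()].
#' @param center Heavy-atom index to start from.
#' @param max_dist Maximum path length to report (`>= 0`).
#' @return Named integer vector mapping atom index to distance; the center
#'   maps to 0.  Atoms further than `max_dist` (or disconnected) are absent.
#' @export
topo_distances <- function(mol, center, max_dist) {
  n <- nrow(mol$atoms)
  if (length(center) != 1L || is.na(center) || center < 1L || center > n)
    stop("center atom index out of range 1..", n)
  if (mol$atoms$element[center] == "H")
    stop("center must be a heavy atom")
  if (max_dist < 0L) stop("max_dist must be >= 0")
  heavy <- mol$atoms$element != "H"
  adj <- vector("list", n)
  b <- mol$bonds
  keep <- heavy[b$a] & heavy[b$b]
  for (i in which(keep)) {
    adj[[b$a[i]]] <- c(adj[[b$a[i]]], b$b[i])
    adj[[b$b[i]]] <- c(adj[[b$b[i]]], b$a[i])
  }
  dist <- rep(NA_integer_, n)
  dist[center] <- 0L
  frontier <- center
  d <- 0L
  while (length(frontier) && d < max_dist) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  found <- which(!is.na(dist))
  stats::setNames(dist[found], found)
}
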