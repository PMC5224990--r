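#' Per-atom population set for three electron states
#'
#' Holds, for every atom of one compound, the Mulliken charges of the neutral
#' (N electrons), anionic (N+1) and cationic (N-1) states, plus an optional
#' per-atom surface area.  The Mulliken population of atom A in state s is
#' P_A(s) = Z_A - q_A(s), so charge differences between states give the
#' condensed Fukui indices directly.
#'
#' @param compound_id Compound name.
#' @param atoms Data frame with columns `atom_index`, `element`, `q_N`,
#'   `q_Np1`, `q_Nm1` and optionally `surface_area`.
#' @param spin_labels Optional named character vector of per-state spin
#'   metadata (kept verbatim, not interpreted).
#' @return An object of class `population_set`.
#' @export
population_set <- function(compound_id, atoms, spin_labels = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("atom_index", "element", "q_N", "q_Np1", "q_Nm1")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("population set missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$surface_area)) atoms$surface_area <- NA_real_
  atoms$atom_index <- as.integer(atoms$atom_index)
  if (anyDuplicated(atoms$atom_index))
    stop("duplicate atom_index in population set for ", compound_id)
  for (col in c("q_N", "q_Np1", "q_Nm1")) {
    atoms[[col]] <- as.numeric(atoms[[col]])
    if (anyNA(atoms[[col]]))
      stop("missing ", col, " charge state for compound ", compound_id)
  }
  z <- .ELEMENT_Z[atoms$element]
  if (anyNA(z))
    stop("unknown element(s) in population set: ",
         paste(unique(atoms$element[is.na(z)]), collapse = ", "))
  atoms$Z <- as.integer(z)
  structure(list(compound_id = as.character(compound_id),
                 atoms = atoms[, c("atom_index", "element", "Z", "q_N",
                                   "q_Np1", "q_Nm1", "surface_area")],
                 spin_labels = spin_labels),
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat("<population_set> ", x$compound_id, ": ", nrow(x$atoms),
      " atoms, three charge states", if (!all(is.na(x$atoms$surface_area)))
        ", surface areas" else "", "\n", sep = "")
  invisible(x)
}

#' Read per-atom population tables from CSV
#'
#' The exchange CSV has one row per (compound, atom) with header
#' `compound_id,atom_index,element,q_N,q_Np1,q_Nm1,surface_area`; the
#' `surface_area` column (or individual cells) may be empty.
#'
#' @param path CSV file path.
#' @return Named list of [population_set()] objects, one per compound.
#' @export
parse_population_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("compound_id", "atom_index", "element", "q_N", "q_Np1", "q_Nm1")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("population table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in c("q_N", "q_Np1", "q_Nm1")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) & nzchar(trimws(tab[[col]])))
    if (length(bad))
      stop("non-numeric ", col, " at row ", bad[1L] + 1L, " of ", path)
    if (anyNA(v))
      stop("missing ", col, " at row ",
           which(is.na(v))[1L] + 1L, " of ", path)
    tab[[col]] <- v
  }
  if (is.null(tab$surface_area)) tab$surface_area <- NA_real_
  tab$surface_area <- suppressWarnings(as.numeric(tab$surface_area))
  key <- paste(tab$compound_id, tab$atom_index)
  if (anyDuplicated(key))
    stop("duplicate (compound, atom) key: ", key[duplicated(key)][1L])
  out <- lapply(split(tab, tab$compound_id), function(d) {
    d <- d[order(d$atom_index), ]
    population_set(d$compound_id[1L], d[, -1L])
  })
  out[unique(tab$compound_id)]
}

#' Write population sets to the exchange CSV
#'
#' @param pops A [population_set()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(pops, path) {
  if (inherits(pops, "population_set")) pops <- list(pops)
  rows <- do.call(rbind, lapply(pops, function(p) {
    data.frame(compound_id = p$compound_id,
               p$atoms[, c("atom_index", "element", "q_N", "q_Np1", "q_Nm1",
                           "surface_area")],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract Mulliken charges from quantum-chemistry log text
#'
#' Scans log text for Mulliken charge blocks (a header line containing
#' "Mulliken charges", an optional column-header line, then one
#' `index element charge` row per atom).  When several blocks are present the
#' last one wins, matching the convention that post-optimization values are
#' printed last.
#'
#' @param log Log text (single string or character vector of lines) or a file
#'   path.
#' @param state Which electron state the log describes: `"N"`, `"Np1"` or
#'   `"Nm1"`.  Recorded as an attribute on the result.
#' @param n_atoms Optional expected atom count; a mismatch is an error.
#' @return Named numeric vector of charges (names are atom indices), with
#'   attributes `state` and, if present in the header, `spin`.
#' @export
parse_mulliken_log <- function(log, state = c("N", "Np1", "Nm1"),
                               n_atoms = NULL) {
  state <- match.arg(state)
  lines <- if (length(log) == 1L && !grepl("\n", log, fixed = TRUE) &&
               file.exists(log)) {
    readLines(log, warn = FALSE)
  } else {
    strsplit(paste(log, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  heads <- grep("Mulliken charges", lines, fixed = TRUE)
  heads <- heads[!grepl("Sum of", lines[heads], fixed = TRUE)]
  if (length(heads) == 0L)
    stop("parse error: no Mulliken charge block found")
  start <- heads[length(heads)]
  spin <- if (grepl("spin", lines[start], ignore.case = TRUE))
    "with spin densities" else NULL
  charges <- numeric()
  i <- start + 1L
  while (i <= length(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) >= 3L && grepl("^[0-9]+$", f[1L]) &&
        f[2L] %in% names(.ELEMENT_Z)) {
      charges[f[1L]] <- as.numeric(f[3L])
    } else if (length(charges) > 0L) {
      break  # block ended (e.g. "Sum of Mulliken charges" line)
    } else if (i > start + 2L) {
      stop("parse error: Mulliken block header found but no atom rows follow")
    }
    i <- i + 1L
  }
  if (length(charges) == 0L)
    stop("parse error: Mulliken block contains no atom rows")
  if (!is.null(n_atoms) && length(charges) != n_atoms)
    stop("alignment error: log has ", length(charges),
         " atoms, molecule has ", n_atoms)
  attr(charges, "state") <- state
  attr(charges, "spin") <- spin
  charges
}

#' Condensed Fukui indices of one atom
#'
#' Finite-difference reactivity indices from the three-state Mulliken
#' populations: f+ = P(N+1) - P(N) (electrophilicity), f- = P(N) - P(N-1)
#' (nucleophilicity) and f0 = (P(N+1) - P(N-1)) / 2 (radical susceptibility).
#' Since P_A(s) = Z_A - q_A(s), these reduce to charge differences and the
#' atomic number cancels.
#'
#' @param pop A [population_set()].
#' @param atom Atom index (omit to get a data frame for all atoms).
#' @return For a single atom, a list with `f_plus`, `f_minus`, `f_zero`; with
#'   `atom = NULL`, a data frame over all atoms.
#' @export
fukui <- function(pop, atom = NULL) {
  a <- pop$atoms
  if (!is.null(atom)) {
    i <- match(atom, a$atom_index)
    if (is.na(i))
      stop("atom ", atom, " not present in population set for ",
           pop$compound_id)
    a <- a[i, , drop = FALSE]
  }
  f_plus <- a$q_N - a$q_Np1    # P(N+1) - P(N)
  f_minus <- a$q_Nm1 - a$q_N   # P(N) - P(N-1)
  f_zero <- (f_plus + f_minus) / 2
  if (!is.null(atom))
    return(list(f_plus = f_plus, f_minus = f_minus, f_zero = f_zero))
  data.frame(atom_index = a$atom_index, element = a$element,
             f_plus = f_plus, f_minus = f_minus, f_zero = f_zero)
}

#' The 5-feature quantum-mechanics vector of one atom
#'
#' In order: neutral-state Mulliken charge `q_N`, Fukui `f_plus`, `f_minus`,
#' `f_zero`, and the per-atom `surface_area` (`NA` when the population set
#' carries none; the dataset assembler decides whether to drop the column or
#' impute zero).
#'
#' @inheritParams fukui
#' @return Named numeric vector of length 5.
#' @export
qm_feature_vector <- function(pop, atom) {
  i <- match(atom, pop$atoms$atom_index)
  if (is.na(i))
    stop("atom ", atom, " not present in population set for ",
         pop$compound_id)
  f <- fukui(pop, atom)
  c(q_N = pop$atoms$q_N[i], f_plus = f$f_plus, f_minus = f$f_minus,
    f_zero = f$f_zero, surface_area = pop$atoms$surface_area[i])
}

#' Dense descending ranks (rank 1 = largest; ties share the better rank)
#'
#' @param x Numeric vector.
#' @return Integer vector of dense ranks.
#' @export
rank_descending <- function(x) {
  if (length(x) == 0L) stop("cannot rank an empty vector")
  u <- sort(unique(x), decreasing = TRUE)
  match(x, u)
}

#' Intramolecular nucleophilicity ranking
#'
#' Ranks candidate atoms of one molecule by their f- (nucleophilicity) in
#' descending order.  FMO oxidation sites tend to carry the first- or
#' second-ranked f- of their molecule, which makes this ranking a useful
#' model-free screen.
#'
#' @param pop A [population_set()].
#' @param candidates Atom indices to rank (>= 1 of them).
#' @return Data frame with `atom_index`, `element`, `f_minus`, `rank`
#'   (dense, 1 = most nucleophilic; ties share the better rank).
#' @export
rank_fukui_minus <- function(pop, candidates) {
  if (length(candidates) == 0L) stop("candidate list is empty")
  i <- match(candidates, pop$atoms$atom_index)
  if (anyNA(i))
    stop("candidate atom(s) not in population set: ",
         paste(candidates[is.na(i)], collapse = ", "))
  f <- fukui(pop)
  fm <- f$f_minus[match(candidates, f$atom_index)]
  data.frame(atom_index = candidates,
             element = pop$atoms$element[i],
             f_minus = fm,
             rank = rank_descending(fm),
             stringsAsFactors = FALSE)
}
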