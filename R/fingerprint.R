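#' Per-atom Molprint2D circular fingerprint
#'
#' Describes one center atom by the frequency of SYBYL atom types found at
#' successive bond-distance layers around it.  The scope is restricted to two
#' bond lengths: layer 1 holds the direct neighbors, layer 2 the atoms two
#' bonds away.  Hydrogens never count as neighbors.
#'
#' @param mol A typed [molecule()] (see [assign_sybyl_types()]).
#' @param center Heavy-atom index of the center.
#' @param max_layer Number of layers, 0..2 (default 2).
#' @param table A [sybyl_type_table()].
#' @param layer_mode `"exact"` (default) counts each neighbor once, at its
#'   shortest bond distance; `"cumulative"` counts at layer d every atom
#'   within d bonds, so layer 2 also re-counts the direct neighbors.
#' @return An object of class `atom_fingerprint`: the center's type index and
#'   per-layer named count vectors (names are type indices).
#' @examples
#' mol <- read_molecule("CCO", "smiles", compound_id = "ethanol")
#' molprint2d(mol, center = 1)
#' @export
molprint2d <- function(mol, center, max_layer = 2L,
                       table = sybyl_type_table(),
                       layer_mode = c("exact", "cumulative")) {
  layer_mode <- match.arg(layer_mode)
  if (!max_layer %in% 0:2) stop("max_layer must be 0, 1 or 2")
  if (center < 1L || center > nrow(mol$atoms))
    stop("center atom index out of range")
  if (mol$atoms$element[center] == "H")
    stop("fingerprint centers must be heavy atoms (potential SOMs)")
  typed <- mol$atoms$sybyl_type
  if (anyNA(typed) || any(!nzchar(typed)))
    stop("molecule is not fully typed; call assign_sybyl_types() first")
  dist <- topo_distances(mol, center, max_layer)
  idx_of <- function(atoms) sybyl_index(typed[atoms], table)
  layers <- list()
  for (d in seq_len(max_layer)) {
    members <- as.integer(names(dist))[if (layer_mode == "exact") dist == d
                                       else dist >= 1L & dist <= d]
    if (length(members)) {
      counts <- table(idx_of(members))
      v <- stats::setNames(as.integer(counts), names(counts))
      layers[[as.character(d)]] <- v[order(as.integer(names(v)))]
    } else {
      layers[[as.character(d)]] <- stats::setNames(integer(), character())
    }
  }
  structure(list(center_type_index = idx_of(center),
                 layers = layers, max_layer = as.integer(max_layer)),
            class = "atom_fingerprint")
}

#' Canonical Molprint2D text form
#'
#' The text form lists the center's type index, then one `layer-frequency-type`
#' triplet per (layer, neighbor type), layers ascending and type indices
#' ascending within a layer, each field terminated by `";"`, e.g.
#' `"1; 1-1-2; 2-1-9;"`.
#'
#' @param fp An `atom_fingerprint`.
#' @return A single string.
#' @export
fp_text <- function(fp) {
  parts <- sprintf("%d;", fp$center_type_index)
  for (d in names(fp$layers)) {
    v <- fp$layers[[d]]
    if (length(v))
      parts <- c(parts, sprintf("%s-%d-%s;", d, unname(v), names(v)))
  }
  paste(parts, collapse = " ")
}

#' @rdname fp_text
#' @param text Text form to parse back into an `atom_fingerprint`.
#' @param max_layer Number of layers the fingerprint declares (defaults to the
#'   deepest layer present in the text, at least 2).
#' @export
parse_fp_text <- function(text, max_layer = NULL) {
  fields <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  fields <- fields[nzchar(fields)]
  if (length(fields) == 0L) stop("empty fingerprint text")
  center <- suppressWarnings(as.integer(fields[1L]))
  if (is.na(center)) stop("malformed fingerprint text: bad center field '",
                          fields[1L], "'")
  triplets <- fields[-1L]
  layers <- list()
  max_seen <- 0L
  for (tr in triplets) {
    p <- suppressWarnings(as.integer(strsplit(tr, "-", fixed = TRUE)[[1]]))
    if (length(p) != 3L || anyNA(p))
      stop("malformed fingerprint triplet '", tr, "'")
    d <- as.character(p[1L])
    max_seen <- max(max_seen, p[1L])
    layers[[d]] <- c(layers[[d]], stats::setNames(p[2L], p[3L]))
  }
  if (is.null(max_layer)) max_layer <- max(max_seen, 2L)
  out <- list()
  for (d in seq_len(max_layer)) {
    v <- layers[[as.character(d)]]
    if (is.null(v)) v <- stats::setNames(integer(), character())
    out[[as.character(d)]] <- v[order(as.integer(names(v)))]
  }
  structure(list(center_type_index = center, layers = out,
                 max_layer = as.integer(max_layer)),
            class = "atom_fingerprint")
}

#' @export
print.atom_fingerprint <- function(x, ...) {
  cat("<atom_fingerprint> ", fp_text(x), "\n", sep = "")
  invisible(x)
}

# Column labels of the full 53 x 3 attribute block: the bare type code for
# the center block, "I-<code>" for layer 1 and "II-<code>" for layer 2.
.fp_full_labels <- function(table = sybyl_type_table()) {
  c(table$code, paste0("I-", table$code), paste0("II-", table$code))
}

#' Encode a fingerprint as a fixed-length numeric vector
#'
#' The 53 SYBYL types give 53 x 3 = 159 positions: positions 1..53 are a
#' one-hot of the center type, 54..106 the layer-1 frequencies by type index
#' and 107..159 the layer-2 frequencies.
#'
#' @param fp An `atom_fingerprint` (from [molprint2d()] or [parse_fp_text()]).
#' @param table A [sybyl_type_table()].
#' @return Named numeric vector of length 159.
#' @export
encode_fingerprint <- function(fp, table = sybyl_type_table()) {
  n <- nrow(table)
  v <- stats::setNames(numeric(3L * n), .fp_full_labels(table))
  if (fp$center_type_index < 1L || fp$center_type_index > n)
    stop("center type index out of range 1..", n)
  v[fp$center_type_index] <- 1
  for (d in c("1", "2")) {
    lay <- fp$layers[[d]]
    if (is.null(lay) || !length(lay)) next
    t_idx <- as.integer(names(lay))
    if (any(t_idx < 1L | t_idx > n))
      stop("layer ", d, " type index out of range 1..", n)
    v[(as.integer(d)) * n + t_idx] <- as.numeric(lay)
  }
  v
}

#' Fingerprint attribute matrix for a set of candidate atoms
#'
#' @param mols List of typed [molecule()] objects.
#' @param candidates Data frame with columns `compound_id`, `atom_index`.
#' @param table A [sybyl_type_table()].
#' @param layer_mode Passed to [molprint2d()].
#' @return Numeric matrix, one row per candidate (rownames
#'   `compound_id:atom_index`), 159 columns.
#' @export
fingerprint_matrix <- function(mols, candidates, table = sybyl_type_table(),
                               layer_mode = "exact") {
  ids <- vapply(mols, function(m) m$compound_id, "")
  miss <- setdiff(unique(candidates$compound_id), ids)
  if (length(miss))
    stop("no molecule for compound(s): ", paste(miss, collapse = ", "))
  mat <- matrix(0, nrow(candidates), 3L * nrow(table),
                dimnames = list(paste(candidates$compound_id,
                                      candidates$atom_index, sep = ":"),
                                .fp_full_labels(table)))
  for (i in seq_len(nrow(candidates))) {
    mol <- mols[[match(candidates$compound_id[i], ids)]]
    fp <- molprint2d(mol, candidates$atom_index[i], 2L, table, layer_mode)
    mat[i, ] <- encode_fingerprint(fp, table)
  }
  mat
}

#' Drop attribute columns that are all zero
#'
#' Fingerprint columns for atom types absent from a dataset (hydrogens,
#' metals, dummy types, ...) carry no information and are removed.  The
#' retained column set is frozen into an `attribute_schema` so that it can be
#' re-applied, never re-fit, to new data: fit it on the training partition
#' only.
#'
#' @param mat Numeric matrix whose columns are the full 159 fingerprint
#'   attributes (e.g. from [fingerprint_matrix()]).
#' @param provenance Optional note recorded in the schema (dataset id, date).
#' @return List with `schema` (an `attribute_schema` data frame: `label`,
#'   `block`, `type_index`, `position`) and `matrix` (the reduced matrix, same
#'   row order, retained columns only).
#' @export
prune_schema <- function(mat, provenance = NULL) {
  if (is.null(dim(mat)) || nrow(mat) == 0L)
    stop("attribute matrix must be non-empty")
  keep <- which(colSums(mat != 0) > 0L)
  labels <- colnames(mat)[keep]
  n_block <- ncol(mat) / 3L
  block <- c("center", "layer1", "layer2")[(keep - 1L) %/% n_block + 1L]
  schema <- data.frame(label = labels, block = block,
                       type_index = as.integer((keep - 1L) %% n_block + 1L),
                       position = as.integer(keep),
                       stringsAsFactors = FALSE)
  attr(schema, "n_full") <- ncol(mat)
  attr(schema, "provenance") <- if (is.null(provenance))
    paste0("pruned ", format(Sys.Date())) else provenance
  class(schema) <- c("attribute_schema", "data.frame")
  list(schema = schema, matrix = mat[, keep, drop = FALSE])
}

#' Apply a stored attribute schema to new data
#'
#' @param schema An `attribute_schema` from [prune_schema()].
#' @param x A full-width attribute matrix or a single full-length vector.
#' @return The reduced matrix (or vector) restricted to the schema's columns.
#' @export
apply_schema <- function(schema, x) {
  n_full <- attr(schema, "n_full")
  if (is.null(dim(x))) {
    if (length(x) != n_full)
      stop("dimension error: expected a length-", n_full, " vector, got ",
           length(x))
    return(x[schema$position])
  }
  if (ncol(x) != n_full)
    stop("dimension error: expected ", n_full, " columns, got ", ncol(x))
  x[, schema$position, drop = FALSE]
}
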