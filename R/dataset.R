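#' Enumerate potential sites of metabolism
#'
#' FMO enzymes oxidize soft nucleophiles, and N- and S-oxidation account for
#' the overwhelming majority of FMO metabolites, so every heavy nitrogen and
#' sulfur atom is a candidate by default.  An exclusion list of SYBYL type
#' codes (shipped empty) can remove chemically implausible candidates, e.g.
#' `exclude_types = "N.am"` to drop amide nitrogens.
#'
#' @param mol A typed [molecule()].
#' @param exclude_types Character vector of SYBYL codes to exclude.
#' @return Integer vector of candidate atom indices, ascending (possibly
#'   empty).
#' @export
enumerate_potential_soms <- function(mol, exclude_types = character()) {
  a <- mol$atoms
  cand <- a$index[a$element %in% c("N", "S")]
  if (length(exclude_types) && length(cand)) {
    cand <- cand[!(a$sybyl_type[cand] %in% exclude_types)]
  }
  sort(cand)
}

.QM_FEATURES <- c("q_N", "f_plus", "f_minus", "f_zero", "surface_area")
.META_COLS <- c("compound_id", "atom_index", "element", "label")

#' Assemble a SOM dataset
#'
#' Joins, for every potential SOM of every molecule, the 5-feature QM block
#' with the (optionally pruned) fingerprint block and the som/nonsom label.
#' Rows are ordered by compound id then atom index, so the result is
#' invariant to the order of the input lists.
#'
#' @param mols List of typed [molecule()] objects.
#' @param pops Named list of [population_set()] objects (as returned by
#'   [parse_population_table()]).
#' @param labels Data frame `compound_id, atom_index, label` with label in
#'   `{som, nonsom}`; candidates without a label become `"unknown"`.  A label
#'   row that does not match an enumerated candidate is an error.
#' @param schema Optional `attribute_schema` from [prune_schema()]; `NULL`
#'   keeps all 159 fingerprint columns (prune after splitting, on the
#'   training partition).
#' @param table A [sybyl_type_table()].
#' @param surface_area_policy What to do when surface areas are missing:
#'   `"drop"` (default) removes the column dataset-wide, `"zero"` imputes 0.
#' @param exclude_types Passed to [enumerate_potential_soms()].
#' @param layer_mode Passed to [molprint2d()].
#' @return A `som_dataset`: a data frame with meta columns
#'   `compound_id, atom_index, element, label` followed by the feature
#'   columns, with attributes `qm_features`, `schema` and `class_convention`
#'   (`"nonsom"`, i.e. non-SOM is class I).
#' @export
assemble_dataset <- function(mols, pops, labels, schema = NULL,
                             table = sybyl_type_table(),
                             surface_area_policy = c("drop", "zero"),
                             exclude_types = character(),
                             layer_mode = "exact") {
  surface_area_policy <- match.arg(surface_area_policy)
  mol_ids <- vapply(mols, function(m) m$compound_id, "")
  cand <- do.call(rbind, lapply(mols, function(m) {
    idx <- enumerate_potential_soms(m, exclude_types)
    if (length(idx) == 0L) return(NULL)
    data.frame(compound_id = m$compound_id, atom_index = idx,
               element = m$atoms$element[idx], stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) stop("no potential SOMs in any molecule")
  cand <- cand[order(cand$compound_id, cand$atom_index), ]
  rownames(cand) <- NULL
  ckey <- paste(cand$compound_id, cand$atom_index)

  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  lkey <- paste(labels$compound_id, labels$atom_index)
  off <- setdiff(lkey, ckey)
  if (length(off))
    stop("label(s) for atoms that are not potential SOMs: ",
         paste(off, collapse = "; "))
  bad <- !(labels$label %in% c("som", "nonsom"))
  if (any(bad))
    stop("labels must be 'som' or 'nonsom', got: ",
         paste(unique(labels$label[bad]), collapse = ", "))
  cand$label <- labels$label[match(ckey, lkey)]
  cand$label[is.na(cand$label)] <- "unknown"

  qm <- matrix(NA_real_, nrow(cand), length(.QM_FEATURES),
               dimnames = list(NULL, .QM_FEATURES))
  for (i in seq_len(nrow(cand))) {
    pop <- pops[[cand$compound_id[i]]]
    if (is.null(pop))
      stop("join error: no population data for compound ",
           cand$compound_id[i])
    qm[i, ] <- qm_feature_vector(pop, cand$atom_index[i])
  }
  qm_features <- .QM_FEATURES
  if (anyNA(qm[, "surface_area"])) {
    if (surface_area_policy == "drop") {
      qm <- qm[, setdiff(colnames(qm), "surface_area"), drop = FALSE]
      qm_features <- setdiff(qm_features, "surface_area")
    } else {
      qm[is.na(qm[, "surface_area"]), "surface_area"] <- 0
    }
  }

  fp <- fingerprint_matrix(mols[match(unique(cand$compound_id), mol_ids)],
                           cand, table, layer_mode)
  if (!is.null(schema)) fp <- apply_schema(schema, fp)

  ds <- cbind(cand, as.data.frame(qm), as.data.frame(fp, check.names = FALSE),
              stringsAsFactors = FALSE)
  rownames(ds) <- NULL
  structure(ds, qm_features = qm_features, schema = schema,
            class_convention = "nonsom",
            class = c("som_dataset", "data.frame"))
}

#' Feature matrix / labels of a SOM dataset
#' @param ds A `som_dataset`.
#' @return `dataset_features()`: numeric matrix (rows follow the dataset);
#'   `dataset_labels()`: factor with levels `nonsom`, `som` (`unknown` rows
#'   give `NA`).
#' @export
dataset_features <- function(ds) {
  as.matrix(ds[, setdiff(names(ds), .META_COLS), drop = FALSE])
}

#' @rdname dataset_features
#' @export
dataset_labels <- function(ds) {
  factor(ds$label, levels = c("nonsom", "som"))
}

#' Prune the fingerprint block of an assembled dataset
#'
#' Convenience wrapper: runs [prune_schema()] on the dataset's fingerprint
#' columns (the QM block is never pruned) and returns the reduced dataset
#' together with the frozen schema, which should then be applied to any other
#' partition with [apply_schema_dataset()].
#'
#' @param ds A `som_dataset` still carrying the full 159 fingerprint columns.
#' @param provenance Optional note stored in the schema.
#' @return List with `schema` and `dataset`.
#' @export
prune_dataset <- function(ds, provenance = NULL) {
  qm <- attr(ds, "qm_features")
  fp_cols <- setdiff(names(ds), c(.META_COLS, qm))
  pr <- prune_schema(as.matrix(ds[, fp_cols, drop = FALSE]), provenance)
  out <- cbind(ds[, c(.META_COLS, qm), drop = FALSE],
               as.data.frame(pr$matrix, check.names = FALSE))
  rownames(out) <- NULL
  structure(out, qm_features = qm, schema = pr$schema,
            class_convention = attr(ds, "class_convention"),
            class = c("som_dataset", "data.frame"))
  list(schema = pr$schema,
       dataset = structure(out, qm_features = qm, schema = pr$schema,
                           class_convention = attr(ds, "class_convention"),
                           class = c("som_dataset", "data.frame")))
}

#' @rdname prune_dataset
#' @param schema An `attribute_schema` fitted on the training partition.
#' @export
apply_schema_dataset <- function(schema, ds) {
  qm <- attr(ds, "qm_features")
  fp_cols <- setdiff(names(ds), c(.META_COLS, qm))
  red <- apply_schema(schema, as.matrix(ds[, fp_cols, drop = FALSE]))
  out <- cbind(ds[, c(.META_COLS, qm), drop = FALSE],
               as.data.frame(red, check.names = FALSE))
  rownames(out) <- NULL
  structure(out, qm_features = qm, schema = schema,
            class_convention = attr(ds, "class_convention"),
            class = c("som_dataset", "data.frame"))
}

#' Split a dataset into training and test partitions by compound
#'
#' Splitting is always by compound: all instances of a molecule land in the
#' same partition, so no molecule straddles the split.  Either supply an
#' explicit assignment (as the original protocol did with a published
#' randomization list) or a seed plus a test fraction for a reproducible
#' random split.
#'
#' @param ds A `som_dataset`.
#' @param assignment Data frame `compound_id, partition` with partition in
#'   `{train, test}` covering every compound; or `NULL` for seeded mode.
#' @param seed Integer seed (seeded mode).
#' @param test_fraction Fraction of compounds sent to the test set (seeded
#'   mode, default 0.5).
#' @return List with `train` and `test` datasets (either may have 0 rows).
#' @export
split_dataset <- function(ds, assignment = NULL, seed = NULL,
                          test_fraction = 0.5) {
  compounds <- unique(ds$compound_id)
  if (!is.null(assignment)) {
    assignment <- as.data.frame(assignment, stringsAsFactors = FALSE)
    unknown <- setdiff(assignment$compound_id, compounds)
    if (length(unknown))
      stop("assignment names unknown compound(s): ",
           paste(unknown, collapse = ", "))
    uncovered <- setdiff(compounds, assignment$compound_id)
    if (length(uncovered))
      stop("assignment does not cover compound(s): ",
           paste(uncovered, collapse = ", "))
    if (!all(assignment$partition %in% c("train", "test")))
      stop("partition must be 'train' or 'test'")
    test_ids <- assignment$compound_id[assignment$partition == "test"]
  } else {
    if (is.null(seed)) stop("supply either an assignment or a seed")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    n_test <- round(length(compounds) * test_fraction)
    test_ids <- sample(compounds, n_test)
  }
  keep_attrs <- function(d) {
    structure(d, qm_features = attr(ds, "qm_features"),
              schema = attr(ds, "schema"),
              class_convention = attr(ds, "class_convention"),
              class = c("som_dataset", "data.frame"))
  }
  in_test <- ds$compound_id %in% test_ids
  list(train = keep_attrs(ds[!in_test, , drop = FALSE]),
       test = keep_attrs(ds[in_test, , drop = FALSE]))
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read / write SOM datasets as CSV or ARFF
#'
#' CSV keeps full numeric precision; ARFF (the format of the WEKA workbench)
#' declares the class attribute as nominal `{nonsom,som}`.  Meta columns
#' `compound_id` and `atom_index` are carried as ordinary attributes.
#'
#' @param ds A `som_dataset`.
#' @param path Output file.
#' @return `path` invisibly for writers; a `som_dataset` for readers.
#' @export
write_dataset_csv <- function(ds, path) {
  out <- as.data.frame(ds, check.names = FALSE)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 17,
                                                   format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  .as_som_dataset(tab)
}

#' @rdname write_dataset_csv
#' @export
write_dataset_arff <- function(ds, path) {
  out <- as.data.frame(ds, check.names = FALSE)
  out$label <- factor(out$label, levels = c("nonsom", "som", "unknown"))
  out$label <- droplevels(out$label)
  foreign::write.arff(out, path)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_arff <- function(path) {
  tab <- foreign::read.arff(path)
  tab$label <- as.character(tab$label)
  tab$compound_id <- as.character(tab$compound_id)
  tab$element <- as.character(tab$element)
  .as_som_dataset(tab)
}

.as_som_dataset <- function(tab) {
  miss <- setdiff(.META_COLS, names(tab))
  if (length(miss))
    stop("dataset file missing column(s): ", paste(miss, collapse = ", "))
  feat <- setdiff(names(tab), .META_COLS)
  structure(tab, qm_features = intersect(.QM_FEATURES, feat), schema = NULL,
            class_convention = "nonsom",
            class = c("som_dataset", "data.frame"))
}

#' Read a labels CSV (`compound_id,atom_index,label`)
#' @param path CSV path.
#' @return Data frame with the three columns.
#' @export
read_labels <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("compound_id", "atom_index", "label"), names(tab))
  if (length(miss))
    stop("labels file missing column(s): ", paste(miss, collapse = ", "))
  tab$atom_index <- as.integer(tab$atom_index)
  tab
}
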