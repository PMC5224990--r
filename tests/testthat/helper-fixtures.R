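# Shared in-code fixtures and independent oracles.

# Linear chain molecule with explicit SYBYL types (no Open Babel involved).
path_molecule <- function(elements, types = NULL, id = "chain") {
  n <- length(elements)
  atoms <- data.frame(index = seq_len(n), element = elements,
                      stringsAsFactors = FALSE)
  if (!is.null(types)) atoms$sybyl_type <- types
  bonds <- if (n > 1L) {
    data.frame(a = seq_len(n - 1L), b = 2:n, order = "single")
  } else {
    data.frame(a = integer(), b = integer(), order = character())
  }
  molecule(id, atoms, bonds)
}

# Random heavy-atom tree with types drawn straight from the type table.
random_tree_molecule <- function(n, id = "tree", table = sybyl_type_table()) {
  elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE,
                     prob = c(0.6, 0.2, 0.1, 0.1))
  types <- sample(table$code[1:21], n, replace = TRUE)
  atoms <- data.frame(index = seq_len(n), element = elements,
                      sybyl_type = types, stringsAsFactors = FALSE)
  bonds <- if (n > 1L) {
    data.frame(a = 2:n, b = vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L),
               order = "single")
  } else {
    data.frame(a = integer(), b = integer(), order = character())
  }
  molecule(id, atoms, bonds)
}

# Brute-force all-pairs shortest paths (Floyd-Warshall) over heavy atoms.
fw_distances <- function(mol) {
  heavy <- heavy_atoms(mol)
  n <- nrow(mol$atoms)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    if (mol$atoms$element[b$a[i]] == "H" ||
        mol$atoms$element[b$b[i]] == "H") next
    d[b$a[i], b$b[i]] <- 1
    d[b$b[i], b$a[i]] <- 1
  }
  for (k in heavy) for (i in heavy) for (j in heavy) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Build a som_dataset directly from a feature matrix (model-layer tests).
make_ds <- function(x, labels, compound_id = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(compound_id)) compound_id <- paste0("cmp", seq_len(nrow(x)))
  ds <- cbind(data.frame(compound_id = compound_id,
                         atom_index = seq_len(nrow(x)),
                         element = "N", label = labels,
                         stringsAsFactors = FALSE),
              as.data.frame(x, check.names = FALSE))
  structure(ds, qm_features = character(), schema = NULL,
            class_convention = "nonsom",
            class = c("som_dataset", "data.frame"))
}

# Two well-separated 2-D Gaussian blobs.
blob_dataset <- function(n_per_class = 20, sep = 8, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
             matrix(rnorm(2 * n_per_class, mean = sep), ncol = 2))
  make_ds(x, rep(c("nonsom", "som"), each = n_per_class))
}

# Random internally consistent population set (no planted signal).
random_population_set <- function(n, id = "rnd") {
  el <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  q_N <- rnorm(n, 0, 0.3)
  f_minus <- rnorm(n, 0, 0.05); f_minus <- f_minus + (1 - sum(f_minus)) / n
  f_plus <- rnorm(n, 0, 0.05); f_plus <- f_plus + (1 - sum(f_plus)) / n
  population_set(id, data.frame(atom_index = seq_len(n), element = el,
                                q_N = q_N, q_Np1 = q_N - f_plus,
                                q_Nm1 = q_N + f_minus,
                                surface_area = runif(n, 5, 40)))
}
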