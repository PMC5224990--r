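#' Specification of a synthetic fixture study
#'
#' The generator emulates what the pipeline actually consumes: valence-legal
#' heavy-atom molecular graphs, and per-atom three-state charge tables whose
#' f- (nucleophilicity) carries a planted additive signal at labeled SOM
#' atoms.  Electron-count consistency is enforced exactly, so per compound
#' the f-, f+ and f0 indices each sum to 1.
#'
#' @param n_compounds Number of molecules (default 60).
#' @param atoms_range Range of heavy atoms per molecule (default 8..16).
#' @param het_fraction Fraction of non-carbon heavy atoms (default 0.25).
#' @param som_rate Probability that a candidate N/S atom is labeled SOM
#'   (default 0.35, the SOM prevalence of the published dataset).
#' @param effect_size Additive shift delta applied to f- at SOM atoms before
#'   noise (dimensionless; 0 means no signal).
#' @param noise_sd Gaussian noise sd sigma on the raw Fukui draws (> 0).
#' @param seed Integer seed; together with the other fields it fully
#'   determines every generated output.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_compounds = 60L, atoms_range = c(8L, 16L),
                         het_fraction = 0.25, som_rate = 0.35,
                         effect_size = 0.3, noise_sd = 0.02, seed = 1L) {
  if (som_rate <= 0 || som_rate >= 1) stop("som_rate must be in (0, 1)")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (n_compounds < 1L) stop("need at least one compound")
  structure(list(n_compounds = as.integer(n_compounds),
                 atoms_range = as.integer(atoms_range),
                 het_fraction = het_fraction, som_rate = som_rate,
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Valence caps for single-bonded heavy-atom trees.
.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L)

#' Generate random valence-legal molecules
#'
#' Each molecule is a random connected heavy-atom tree over C/N/O/S with
#' single bonds, guaranteed to contain at least one N or S candidate, typed
#' through the same Open Babel path as real input.
#'
#' @param spec A [fixture_spec()].
#' @return List of typed [molecule()] objects with ids `fx001`, `fx002`, ...
#' @export
gen_molecules <- function(spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  het <- spec$het_fraction
  elem_prob <- c(C = 1 - het, N = het * 0.5, S = het * 0.2, O = het * 0.3)
  ids <- sprintf("fx%03d", seq_len(spec$n_compounds))
  sdf <- character(spec$n_compounds)
  for (i in seq_len(spec$n_compounds)) {
    n <- sample(seq(spec$atoms_range[1L], spec$atoms_range[2L]), 1L)
    el <- sample(names(elem_prob), n, replace = TRUE, prob = elem_prob)
    if (!any(el %in% c("N", "S")))
      el[sample(n, 1L)] <- sample(c("N", "S"), 1L, prob = c(0.7, 0.3))
    free <- .VALENCE[el]
    parent <- integer(0)
    for (a in seq_len(n)[-1L]) {
      open <- which(free[seq_len(a - 1L)] > 0L)
      if (length(open) == 0L)
        stop("generation error: no open valence left at atom ", a)
      p <- open[sample.int(length(open), 1L)]
      parent <- c(parent, p)
      free[p] <- free[p] - 1L
      free[a] <- free[a] - 1L
    }
    bonds <- if (n > 1L) {
      data.frame(a = 2:n, b = parent, order = "single",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(a = integer(), b = integer(), order = character())
    }
    mol <- molecule(ids[i], data.frame(index = seq_len(n), element = el,
                                       stringsAsFactors = FALSE), bonds)
    sdf[i] <- .sdf_text(mol)
  }
  read_molecules(paste(sdf, collapse = ""), "sdf", compound_id = ids)
}

#' Pinned real-drug fixtures
#'
#' A small library of FMO substrates and non-substrates parsed from SMILES:
#' benzydamine (3 candidate N), voriconazole (5 N), K11777 (4 N + 1 S),
#' alvameline (5 N) and tozasertib.
#'
#' @return Named list of typed [molecule()] objects.
#' @export
pinned_molecules <- function() {
  smi <- c(
    benzydamine = "CN(C)CCCOC1=NN(CC2=CC=CC=C2)C3=CC=CC=C13",
    voriconazole = "CC(C1=NC=NC=C1F)C(CN2C=NC=N2)(C3=C(C=C(C=C3)F)F)O",
    k11777 = paste0("CN1CCN(CC1)C(=O)NC(CC2=CC=CC=C2)C(=O)NC(CCC3=CC=CC=C3)",
                    "/C=C/S(=O)(=O)C4=CC=CC=C4"),
    alvameline = "CCN1C(=NN=N1)C2=CCCN(C2)C",
    tozasertib = paste0("CC1=CC(=NN1)NC2=NC(=NC(=N2)N3CCN(CC3)CC(=O)NC4CC4)",
                        "SC5=CC=CC=C5"))
  mols <- read_molecules(paste(smi, names(smi), sep = "\t", collapse = "\n"),
                         "smiles")
  stats::setNames(mols, names(smi))
}

#' Draw SOM labels for the candidates of generated molecules
#'
#' @param mols List of molecules.
#' @param spec A [fixture_spec()]; each candidate N/S atom is labeled `som`
#'   with probability `som_rate` (seeded).
#' @return Data frame `compound_id, atom_index, label`.
#' @export
gen_som_labels <- function(mols, spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)
  do.call(rbind, lapply(mols, function(m) {
    cand <- enumerate_potential_soms(m)
    if (length(cand) == 0L) return(NULL)
    data.frame(compound_id = m$compound_id, atom_index = cand,
               label = ifelse(stats::runif(length(cand)) < spec$som_rate,
                              "som", "nonsom"),
               stringsAsFactors = FALSE)
  }))
}

#' Generate internally consistent population sets with a planted signal
#'
#' Baseline charges are element-typical constants plus Gaussian noise.  Raw
#' per-atom f- draws get `effect_size` added at labeled SOM atoms, and each
#' of the f-, f+ vectors is then shifted uniformly so it sums to exactly 1
#' per compound (the N to N-1 and N to N+1 transitions each move exactly one
#' electron); the uniform shift preserves all between-atom differences.
#' Charge states are reconstructed from the shifted indices, so the
#' consistency invariants hold by construction.
#'
#' @param mols List of molecules (typed or not; only the heavy-atom table is
#'   used).
#' @param labels Data frame `compound_id, atom_index, label`; every `som`
#'   label must refer to a candidate N/S atom.
#' @param spec A [fixture_spec()].
#' @return Named list of [population_set()] objects.
#' @export
gen_populations <- function(mols, labels, spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 2L)
  base_q <- c(C = 0.08, N = -0.45, O = -0.55, S = 0.05)
  out <- lapply(mols, function(m) {
    heavy <- heavy_atoms(m)
    el <- m$atoms$element[heavy]
    n <- length(heavy)
    lab <- labels[labels$compound_id == m$compound_id, , drop = FALSE]
    cand <- enumerate_potential_soms(m)
    off <- setdiff(lab$atom_index, cand)
    if (length(off))
      stop("consistency error: label for non-candidate atom(s) ",
           paste(off, collapse = ", "), " of ", m$compound_id)
    is_som <- heavy %in% lab$atom_index[lab$label == "som"]
    q_N <- unname(base_q[el]) + stats::rnorm(n, 0, 0.05)
    raw_minus <- stats::rnorm(n, 0, spec$noise_sd) +
      spec$effect_size * is_som
    f_minus <- raw_minus + (1 - sum(raw_minus)) / n
    raw_plus <- stats::rnorm(n, 0, spec$noise_sd)
    f_plus <- raw_plus + (1 - sum(raw_plus)) / n
    population_set(m$compound_id, data.frame(
      atom_index = heavy, element = el, q_N = q_N,
      q_Np1 = q_N - f_plus, q_Nm1 = q_N + f_minus,
      surface_area = stats::runif(n, 5, 40), stringsAsFactors = FALSE))
  })
  stats::setNames(out, vapply(mols, function(m) m$compound_id, ""))
}

#' Render a population set as quantum-chemistry log snippets
#'
#' Emits one Mulliken-charge block per electron state in the standard log
#' layout (header, column line, `index element charge` rows, trailing sum
#' line).  Charges are printed with 17 significant digits so that
#' [parse_mulliken_log()] inverts the generator exactly.
#'
#' @param pop A [population_set()].
#' @return Named character vector with elements `N`, `Np1`, `Nm1`.
#' @export
gen_log_fixture <- function(pop) {
  a <- pop$atoms
  if (nrow(a) == 0L) stop("cannot render a log for an empty molecule")
  block <- function(q) {
    paste(c(" Mulliken charges:",
            "               1",
            sprintf("%6d  %-2s  %s", a$atom_index, a$element,
                    formatC(q, digits = 17, format = "g")),
            sprintf(" Sum of Mulliken charges = %s",
                    formatC(sum(q), digits = 17, format = "g"))),
          collapse = "\n")
  }
  c(N = block(a$q_N), Np1 = block(a$q_Np1), Nm1 = block(a$q_Nm1))
}

#' Run a complete synthetic signal-recovery study
#'
#' Generates molecules, labels and populations from `spec`, assembles the
#' dataset, splits it by compound, prunes the fingerprint schema on the
#' training half, optionally grid-searches C and gamma by 10-fold CV AUC,
#' trains the final model and evaluates it on the held-out compounds.
#'
#' @param spec A [fixture_spec()].
#' @param grid `TRUE` to tune C/gamma on a small grid, `FALSE` to use `cfg`
#'   as is.
#' @param cfg Base [model_config()].
#' @param test_fraction Compound fraction held out (default 0.5).
#' @param C_grid,gamma_grid Grids used when `grid = TRUE`.
#' @param folds CV folds for the grid search.
#' @return List with `report` (held-out `eval_report`), `model`, `cfg`,
#'   `grid_table` (or `NULL`), `train`, `test`.
#' @export
run_fixture_study <- function(spec = fixture_spec(), grid = TRUE,
                              cfg = model_config(seed = spec$seed),
                              test_fraction = 0.5,
                              C_grid = c(1, 8, 64),
                              gamma_grid = c("1/n", 0.05, 0.5),
                              folds = 10L) {
  mols <- gen_molecules(spec)
  labels <- gen_som_labels(mols, spec)
  pops <- gen_populations(mols, labels, spec)
  ds <- assemble_dataset(mols, pops, labels)
  parts <- split_dataset(ds, seed = spec$seed, test_fraction = test_fraction)
  pr <- prune_dataset(parts$train, provenance = "fixture study")
  train <- pr$dataset
  test <- apply_schema_dataset(pr$schema, parts$test)
  grid_table <- NULL
  if (grid) {
    gs <- grid_search(train, C_grid = C_grid, gamma_grid = gamma_grid,
                      folds = folds, seed = spec$seed, cfg_base = cfg)
    cfg <- gs$best
    grid_table <- gs$table
  }
  model <- train_svm(train, cfg)
  list(report = evaluate(model, test), model = model, cfg = cfg,
       grid_table = grid_table, train = train, test = test)
}
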