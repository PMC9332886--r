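# Synthetic inputs for testing the pipeline end-to-end: planted-signal
# descriptor matrices emulating the statistical regime of a small QSAR
# study (n = 67 train / 17 test, 5 informative descriptors, R2 near 0.83),
# and a toy-molecule suite covering every atom class the descriptor
# grammar uses.

#' Generate a descriptor matrix with a planted linear signal
#'
#' Draws a standard-normal descriptor matrix, plants a k-descriptor linear
#' signal with Gaussian noise whose variance is solved so the population R2
#' equals `target_r2`, and optionally correlates a share of the decoy
#' columns with planted ones to mimic the collinearity of real descriptor
#' pools. The planted block is redrawn (deterministically under the seed)
#' until its pairwise sample correlations all stay below 0.5.
#'
#' @param n compounds (default 84 = 67 train + 17 test).
#' @param p descriptor columns.
#' @param k planted (informative) descriptors.
#' @param target_r2 population coefficient of determination in (0, 1).
#' @param seed RNG seed; regeneration under the same seed is bit-identical.
#' @param decoy_cor correlation of decoy columns with a random planted
#'   column (0 disables; around 0.6 stresses subset selection).
#' @param n_decoy_cor number of decoy columns made collinear.
#' @param intercept intercept of the planted model (default 6, a typical
#'   mid-range pEC50).
#' @param beta_range range of planted coefficient magnitudes (signs are
#'   random). The default keeps magnitudes within 25% of a common scale so
#'   that, at the study's sample size, every planted descriptor is
#'   individually identifiable rather than lost in the noise floor.
#' @return a `planted_dataset`: list with `X` (n x p, columns D0001...),
#'   `y`, `truth` (idx, beta, intercept, sigma, seed, target_r2) and
#'   `achieved_r2` (training-sample OLS R2 on the planted subset).
#' @export
make_planted <- function(n = 84, p = 200, k = 5, target_r2 = 0.83,
                         seed = 1L, decoy_cor = 0, n_decoy_cor = 0,
                         intercept = 6, beta_range = c(0.75, 1.25)) {
  stopifnot(n > k + 2, p >= k)
  if (target_r2 <= 0 || target_r2 >= 1)
    stop("target_r2 must be in (0, 1)")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  idx <- sort(sample.int(p, k))
  if (k > 1) {
    repeat {
      cm <- abs(stats::cor(X[, idx]))
      diag(cm) <- 0
      if (max(cm) < 0.5) break
      X[, idx] <- stats::rnorm(n * k)
    }
  }
  if (decoy_cor > 0 && n_decoy_cor > 0) {
    decoys <- sample(setdiff(seq_len(p), idx), n_decoy_cor)
    for (d in decoys) {
      src <- idx[sample.int(k, 1)]
      X[, d] <- decoy_cor * X[, src] +
        sqrt(1 - decoy_cor^2) * stats::rnorm(n)
    }
  }
  beta <- stats::runif(k, beta_range[1], beta_range[2]) *
    sample(c(-1, 1), k, replace = TRUE)
  signal_var <- sum(beta^2)              # unit-variance independent columns
  sigma <- sqrt(signal_var * (1 - target_r2) / target_r2)
  y <- intercept + drop(X[, idx, drop = FALSE] %*% beta) +
    stats::rnorm(n, sd = sigma)
  colnames(X) <- sprintf("D%04d", seq_len(p))
  rownames(X) <- sprintf("cmp%03d", seq_len(n))
  achieved <- fit_ols(X[, idx, drop = FALSE], y)$stats$R2
  structure(
    list(X = X, y = y,
         truth = list(idx = idx, beta = beta, intercept = intercept,
                      sigma = sigma, seed = seed, target_r2 = target_r2),
         achieved_r2 = achieved),
    class = "planted_dataset"
  )
}

#' @export
print.planted_dataset <- function(x, ...) {
  cat(sprintf(
    "<planted_dataset> %d x %d, k = %d planted (sigma = %.3f, sample R2 = %.3f)\n",
    nrow(x$X), ncol(x$X), length(x$truth$idx), x$truth$sigma, x$achieved_r2))
  invisible(x)
}

#' Write a planted dataset in the pipeline's file formats
#'
#' Emits the descriptor TSV and the activity CSV the pipeline readers
#' consume, so tests exercise the real I/O paths.
#'
#' @param ds a `planted_dataset`.
#' @param dir output directory.
#' @return named list of the file paths, invisibly.
#' @export
write_planted <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- structure(
    list(compound_ids = rownames(ds$X), descriptor_names = colnames(ds$X),
         values = ds$X, provenance = list(engine = "qsarga-synthetic")),
    class = "descriptor_matrix"
  )
  paths <- list(descriptors = file.path(dir, "descriptors.tsv"),
                activity = file.path(dir, "activity.csv"))
  write_descriptor_matrix(dm, paths$descriptors)
  utils::write.csv(
    data.frame(compound_id = rownames(ds$X), pec50 = ds$y),
    paths$activity, row.names = FALSE)
  invisible(paths)
}

#' Toy-molecule suite
#'
#' Small molecules chosen so that every atom class of the typing table
#' (ring carbon, ring sulfur, amide nitrogen, donors, sp2/sp3 carbon,
#' sp2 and non-ring oxygen, lipophilic atoms, hydrogens) occurs somewhere,
#' together with the descriptor names each molecule is a worthwhile probe
#' for. Golden values are computed, not stored: [golden_descriptor_values()]
#' evaluates the suite with the brute-force reference enumerator.
#'
#' @return data frame with `name`, `smiles` and `probes`
#'   (comma-separated descriptor names).
#' @export
toy_molecule_suite <- function() {
  data.frame(
    name = c("methane", "ethane", "ethanol", "acetamide", "thiophene",
             "pyridine", "benzene", "toluene", "phenol", "anisole",
             "aminohexyl_cyclohexane", "thiophene_carboxamide",
             "n_methylacetamide", "chlorobenzene", "morpholine",
             "methyl_acetate"),
    smiles = c("C", "CC", "OCC", "CC(N)=O", "c1ccsc1", "c1ccncc1",
               "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "COc1ccccc1",
               "NCCCCCC1CCCCC1", "NC(=O)c1cccs1", "CNC(C)=O",
               "Clc1ccccc1", "C1COCCN1", "COC(C)=O"),
    probes = c(
      "avg_molweight", "fsp3Csp3C1B", "fdonsp3C2B", "famdNsp2O1B",
      "lipo_ringS_8Bc", "fNringC1B", "fringCH3B", "fringCsp3C1B",
      "fdonringC1B", "fnotringOringC1B", "fNringC6B",
      "lipo_ringS_8Bc,famdNringS2B", "famdNsp3C1B", "fClringC1B",
      "fdonnotringO2B", "fnotringOsp3C1B"),
    stringsAsFactors = FALSE
  )
}

#' Brute-force descriptor reference values for the toy suite
#'
#' Evaluates descriptor names on the toy molecules with
#' [brute_force_descriptor()], an enumeration-based reference path kept
#' deliberately separate from the vectorised engine. Regenerated on every
#' call — never hand-edited.
#'
#' @param suite output of [toy_molecule_suite()] (or a compatible frame).
#' @param descriptors descriptor names to evaluate on every molecule;
#'   defaults to the union of the per-molecule probes.
#' @return data frame: one row per (molecule, descriptor) with the
#'   reference `value`.
#' @export
golden_descriptor_values <- function(suite = toy_molecule_suite(),
                                     descriptors = NULL) {
  if (is.null(descriptors))
    descriptors <- unique(unlist(strsplit(suite$probes, ",")))
  mols <- parse_molecules(suite$smiles, suite$name)
  out <- expand.grid(name = suite$name, descriptor = descriptors,
                     stringsAsFactors = FALSE)
  out$value <- mapply(function(nm, d) {
    brute_force_descriptor(mols[[nm]], d)
  }, out$name, out$descriptor)
  out
}

#' Brute-force descriptor evaluation (reference path)
#'
#' Evaluates a pair-count or charge-sum descriptor by explicit enumeration
#' over all atom pairs using a breadth-first-search distance computed on
#' the spot — no shared code with the engine's matrix path. Intended as the
#' oracle golden values are derived from.
#'
#' @param mol typed `molgraph`.
#' @param name descriptor name.
#' @return numeric scalar.
#' @export
brute_force_descriptor <- function(mol, name) {
  spec <- parse_descriptor(name)
  if (spec$family == "global_property")
    return(mol$molweight / nrow(mol$atoms))
  bfs_dist <- function(start) {
    n <- nrow(mol$atoms)
    d <- rep(Inf, n); d[start] <- 0
    frontier <- start
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in mol$adj[[v]]) {
        if (d[w] > d[v] + 1) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
      }
      frontier <- nxt
    }
    d
  }
  centers <- which(.flag_vector(mol, spec$center))
  targets <- which(.flag_vector(mol, spec$target))
  if (spec$family == "exact_pair_count") {
    cnt <- 0L
    for (a in centers) {
      d <- bfs_dist(a)
      for (b in targets) if (d[b] == spec$distance) cnt <- cnt + 1L
    }
    return(cnt)
  }
  if (spec$family == "charge_sum_within") {
    if (!length(centers)) return(0)
    reached <- logical(nrow(mol$atoms))
    for (a in centers) {
      d <- bfs_dist(a)
      reached <- reached | (d >= 1 & d <= spec$distance)
    }
    return(sum(partial_charges(mol)[intersect(which(reached), targets)]))
  }
  if (spec$family == "geometric_count") {
    mass <- .atomic_masses[mol$atoms$element]
    com <- c(sum(mol$coords3d[, 1] * mass), sum(mol$coords3d[, 2] * mass),
             sum(mol$coords3d[, 3] * mass)) / sum(mass)
    cnt <- 0L
    for (b in targets) {
      if (sqrt(sum((mol$coords3d[b, ] - com)^2)) <= spec$distance)
        cnt <- cnt + 1L
    }
    return(cnt)
  }
  stop("unsupported family for brute-force evaluation")
}
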