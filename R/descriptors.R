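# Distance-constrained pharmacophore-pair descriptors.
#
# Grammar (four families):
#   f<A><B><n>B        ordered pair count: atoms of class B exactly n bonds
#                      from an atom of class A (e.g. fNringC6B, fdonsp3C2B)
#   <cls>_<A>_<n>Bc    sum of partial charges of class-cls atoms within
#                      1..n bonds of any class-A centre (e.g. lipo_ringS_8Bc)
#   com_<B>_<r>A       count of class-B atoms within r Angstrom of the
#                      molecular centre of mass (e.g. com_sp2O_4A)
#   avg_molweight      molecular weight / atom count (explicit-H graph)

# token -> flag-matrix column (longest-match-first tokenisation)
.descriptor_tokens <- c(
  notringO = "nonring_O", ringC = "ring_C", ringS = "ring_S",
  amdN = "amide_N", sp3C = "sp3_C", sp2C = "sp2_C", sp2O = "sp2_O",
  don = "donor", lipo = "lipophilic",
  Cl = "Cl", Br = "Br",
  C = "C", N = "N", O = "O", S = "S", F = "F", I = "I", H = "H"
)

.flag_vector <- function(mol, token) {
  cls <- .descriptor_tokens[[token]]
  if (is.null(cls)) stop(sprintf("unknown atom-class token '%s'", token))
  if (cls %in% colnames(mol$flags)) return(mol$flags[, cls])
  mol$atoms$element == cls
}

# Greedy tokenisation of the concatenated <A><B> part of an f-descriptor.
.tokenize_pair <- function(s) {
  toks <- character()
  vocab <- names(.descriptor_tokens)[order(nchar(names(.descriptor_tokens)),
                                           decreasing = TRUE)]
  while (nzchar(s)) {
    hit <- vocab[startsWith(s, vocab)][1]
    if (is.na(hit)) return(NULL)
    toks <- c(toks, hit)
    s <- substring(s, nchar(hit) + 1L)
  }
  toks
}

#' Parse a descriptor name
#'
#' @param name descriptor name in the pair-count / charge-sum / geometric /
#'   global grammar (see package overview).
#' @return a `descriptor_spec`: list with `name`, `family`, `center`,
#'   `target`, `distance`, `mode`.
#' @export
#' @examples
#' parse_descriptor("fNringC6B")
#' parse_descriptor("lipo_ringS_8Bc")
parse_descriptor <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  spec <- NULL
  if (name == "avg_molweight") {
    spec <- list(name = name, family = "global_property", center = NA,
                 target = NA, distance = NA, mode = NA)
  } else if (grepl("^com_[A-Za-z0-9]+_[0-9]+A$", name)) {
    m <- regmatches(name, regexec("^com_([A-Za-z0-9]+)_([0-9]+)A$", name))[[1]]
    if (is.null(.descriptor_tokens[[m[2]]]))
      stop(sprintf("unknown atom-class token '%s' in '%s'", m[2], name))
    spec <- list(name = name, family = "geometric_count", center = "com",
                 target = m[2], distance = as.numeric(m[3]), mode = "within")
  } else if (grepl("^[A-Za-z0-9]+_[A-Za-z0-9]+_[0-9]+Bc$", name)) {
    m <- regmatches(name,
                    regexec("^([A-Za-z0-9]+)_([A-Za-z0-9]+)_([0-9]+)Bc$",
                            name))[[1]]
    for (tok in m[2:3]) if (is.null(.descriptor_tokens[[tok]]))
      stop(sprintf("unknown atom-class token '%s' in '%s'", tok, name))
    spec <- list(name = name, family = "charge_sum_within", center = m[3],
                 target = m[2], distance = as.integer(m[4]), mode = "within")
  } else if (grepl("^f[A-Za-z0-9]+[0-9]+B$", name)) {
    m <- regmatches(name, regexec("^f([A-Za-z]+[A-Za-z0-9]*?)([0-9]+)B$",
                                  name))[[1]]
    toks <- .tokenize_pair(m[2])
    if (is.null(toks) || length(toks) != 2L)
      stop(sprintf("cannot resolve atom classes in descriptor '%s'", name))
    spec <- list(name = name, family = "exact_pair_count", center = toks[1],
                 target = toks[2], distance = as.integer(m[3]), mode = "exact")
  }
  if (is.null(spec)) stop(sprintf("unknown descriptor name '%s'", name))
  if (spec$family %in% c("exact_pair_count", "charge_sum_within") &&
      spec$distance < 1L)
    stop(sprintf("invalid distance %d in '%s': must be >= 1",
                 spec$distance, name))
  structure(spec, class = "descriptor_spec")
}

#' Count atom pairs at an exact topological distance
#'
#' Number of ordered (centre, target) pairs with shortest-path bond count
#' exactly `n`. Ordered counting means a target atom seen by two centres
#' contributes twice, reproducing the "frequency of occurrence" semantics.
#'
#' @param mol typed `molgraph`.
#' @param center,target atom-class tokens (e.g. `"N"`, `"ringC"`, `"don"`).
#' @param n exact bond count, `n >= 1`.
#' @return non-negative integer.
#' @export
count_exact_pairs <- function(mol, center, target, n) {
  if (n <= 0) stop("invalid descriptor spec: distance must be >= 1")
  ci <- .flag_vector(mol, center)
  ti <- .flag_vector(mol, target)
  if (!any(ci) || !any(ti)) return(0L)
  sum(mol$dist[ci, ti, drop = FALSE] == n)
}

#' Sum partial charges of target-class atoms within n bonds of a centre
#'
#' Sums charges over atoms of the target class whose topological distance
#' to at least one centre atom lies in 1..n. Each qualifying atom is
#' counted once even if several centres reach it. Returns 0 when the
#' molecule has no centre atom.
#'
#' @inheritParams count_exact_pairs
#' @param n maximum bond count (inclusive).
#' @return numeric charge sum (dimensionless electrons).
#' @export
sum_charges_within <- function(mol, center, target, n) {
  if (n <= 0) stop("invalid descriptor spec: distance must be >= 1")
  ci <- .flag_vector(mol, center)
  ti <- .flag_vector(mol, target)
  if (!any(ci) || !any(ti)) return(0)
  d <- mol$dist[ci, , drop = FALSE]
  reach <- apply(d, 2, function(col) any(col >= 1 & col <= n))
  sum(partial_charges(mol)[ti & reach])
}

#' Count target-class atoms within a radius of the centre of mass
#'
#' @inheritParams count_exact_pairs
#' @param r radius in Angstrom.
#' @return non-negative integer.
#' @export
geometric_count <- function(mol, target, r) {
  if (is.null(mol$coords3d))
    stop(structure(
      class = c("qsar_no_geometry", "error", "condition"),
      list(message = sprintf(
        "molecule '%s' carries no 3D coordinates; parse with with_3d = TRUE",
        mol$name), call = sys.call(-1))
    ))
  ti <- .flag_vector(mol, target)
  if (!any(ti)) return(0L)
  mass <- .atomic_masses[mol$atoms$element]
  com <- colSums(mol$coords3d * mass) / sum(mass)
  dd <- sqrt(colSums((t(mol$coords3d) - com)^2))
  sum(ti & dd <= r)
}

#' Average molecular weight
#'
#' Molecular weight divided by the total atom count of the
#' explicit-hydrogen graph.
#'
#' @param mol a `molgraph`.
#' @return positive numeric.
#' @export
avg_molweight <- function(mol) {
  mol$molweight / nrow(mol$atoms)
}

#' Evaluate one descriptor on one molecule
#'
#' @param mol typed `molgraph`.
#' @param spec a `descriptor_spec` or a descriptor name.
#' @return numeric scalar.
#' @export
evaluate_descriptor <- function(mol, spec) {
  if (is.character(spec)) spec <- parse_descriptor(spec)
  switch(spec$family,
    exact_pair_count =
      count_exact_pairs(mol, spec$center, spec$target, spec$distance),
    charge_sum_within =
      sum_charges_within(mol, spec$center, spec$target, spec$distance),
    geometric_count =
      geometric_count(mol, spec$target, spec$distance),
    global_property = avg_molweight(mol),
    stop("unknown descriptor family: ", spec$family)
  )
}

#' Compute a descriptor matrix
#'
#' @param mols list of typed `molgraph` objects.
#' @param specs character vector of descriptor names, or list of
#'   `descriptor_spec`s.
#' @return a `descriptor_matrix`: list with `compound_ids`,
#'   `descriptor_names`, `values` (numeric matrix, compounds x descriptors)
#'   and `provenance`.
#' @export
compute_matrix <- function(mols, specs) {
  if (is.character(specs)) specs <- lapply(specs, parse_descriptor)
  nms <- vapply(specs, `[[`, "", "name")
  ids <- names(mols)
  if (is.null(ids)) ids <- sprintf("mol%03d", seq_along(mols))
  values <- matrix(NA_real_, length(mols), length(specs),
                   dimnames = list(ids, nms))
  for (i in seq_along(mols)) {
    for (j in seq_along(specs)) {
      v <- tryCatch(evaluate_descriptor(mols[[i]], specs[[j]]),
        error = function(e) stop(sprintf(
          "descriptor '%s' failed on molecule '%s': %s",
          nms[j], ids[i], conditionMessage(e)), call. = FALSE))
      values[i, j] <- v
    }
  }
  structure(
    list(compound_ids = ids, descriptor_names = nms, values = values,
         provenance = list(engine = "qsarga",
                           version = as.character(utils::packageVersion("qsarga")),
                           typing = "default_atom_typing")),
    class = "descriptor_matrix"
  )
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d compounds x %d descriptors\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Generate a combinatorial descriptor pool
#'
#' Expands the grammar over an atom-class grid and a range of topological
#' distances, mirroring how atom-pair descriptor pools of around a thousand
#' to two thousand columns arise in practice before objective filtering.
#'
#' @param tokens atom-class tokens to combine.
#' @param bond_range integer bond distances for pair and charge-sum families.
#' @param radii Angstrom radii for geometric counts (empty to skip them).
#' @return character vector of descriptor names.
#' @export
descriptor_pool <- function(tokens = c("C", "N", "O", "S", "H", "F", "Cl",
                                       "ringC", "ringS", "notringO", "amdN",
                                       "don", "sp3C", "sp2O", "lipo"),
                            bond_range = 1:9, radii = integer()) {
  pairs <- expand.grid(a = tokens, b = tokens, n = bond_range,
                       stringsAsFactors = FALSE)
  pool <- c(
    sprintf("f%s%s%dB", pairs$a, pairs$b, pairs$n),
    sprintf("lipo_%s_%dBc", rep(tokens, each = length(bond_range)),
            bond_range),
    if (length(radii))
      sprintf("com_%s_%dA", rep(tokens, each = length(radii)), radii),
    "avg_molweight"
  )
  unique(pool)
}

#' Write a descriptor matrix to TSV
#'
#' First column `compound_id`, one column per descriptor.
#' @param dm a `descriptor_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(dm, path) {
  df <- data.frame(compound_id = dm$compound_ids, dm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor matrix from TSV
#'
#' @param path file written by [write_descriptor_matrix()] (or any TSV with
#'   a `compound_id` first column).
#' @return a `descriptor_matrix`.
#' @export
read_descriptor_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(names(df)[1] == "compound_id")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$compound_id
  if (anyNA(values)) stop("descriptor matrix contains missing values")
  structure(
    list(compound_ids = as.character(df$compound_id),
         descriptor_names = colnames(values), values = values,
         provenance = list(engine = "qsarga", source = path)),
    class = "descriptor_matrix"
  )
}
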