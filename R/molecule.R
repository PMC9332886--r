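# Molecular graphs: parsing, atom typing, topological distances, charges.

# Monoisotopic-free average atomic masses (g/mol), IUPAC 2021 abridged.
.atomic_masses <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

.mol2_options <- function(gen3d = FALSE) {
  nm <- c("h", "partialcharge")
  ar <- c("", "gasteiger")
  if (gen3d) {
    # standard 3D builder + force-field cleanup; coordinates carry small
    # run-to-run jitter, so geometric descriptors are defined as integer
    # counts (robust to sub-Angstrom noise) and SDF coordinates, when
    # supplied, take precedence over embedding
    nm <- c(nm, "gen3d")
    ar <- c(ar, "3")
  }
  data.frame(names = nm, args = ar)
}

.convert_structure <- function(source, from, to, options = NULL) {
  if (is.null(options)) options <- data.frame(names = "h", args = "")
  suppressWarnings(
    ChemmineOB::convertFormat(from, to, source, options = options)
  )
}

#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES string to an explicit-hydrogen molecular graph with
#' perceived aromaticity, SYBYL-style hybridisation, Gasteiger-Marsili
#' partial charges and all-pairs topological (bond-count) distances.
#' Structure interpretation is delegated to Open Babel (via ChemmineOB);
#' graph quantities are computed on the resulting typed graph.
#'
#' @param smiles a single SMILES string.
#' @param name compound identifier stored on the graph.
#' @param with_3d logical; embed force-field-refined 3D coordinates
#'   (needed by geometric descriptors). Embedded coordinates carry small
#'   run-to-run numerical jitter; supply an SDF via
#'   [read_sdf_molecules()] when exact geometric reproducibility matters.
#' @return an object of class `molgraph`: a list with `atoms` (data frame:
#'   element, sybyl, charge, hybridization, in_ring, aromatic,
#'   n_attached_H), `bonds` (data frame: a1, a2, type), `dist` (integer
#'   matrix of shortest-path bond counts), `coords3d` (matrix or NULL),
#'   `molweight`, `smiles` and `name`.
#' @export
#' @examples
#' m <- parse_molecule("OCC", "ethanol")
#' m$dist[1, 3]  # O to terminal C: 2 bonds
parse_molecule <- function(smiles, name = "mol", with_3d = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  src <- paste(smiles, name)
  txt <- .convert_structure(src, "SMI", "MOL2", .mol2_options(with_3d))
  if (!nzchar(txt) || !grepl("@<TRIPOS>ATOM", txt, fixed = TRUE)) {
    stop(structure(
      class = c("qsar_parse_error", "error", "condition"),
      list(message = sprintf("cannot parse SMILES '%s'", smiles),
           call = sys.call(-1), smiles = smiles)
    ))
  }
  mol <- .mol2_to_molgraph(txt, has_coords = with_3d)
  mol$smiles <- smiles
  mol$name <- name
  if (.n_components(mol) > 1L) {
    stop(structure(
      class = c("qsar_multi_component", "error", "condition"),
      list(message = sprintf("multi-component structure '%s'", smiles),
           call = sys.call(-1), smiles = smiles)
    ))
  }
  assign_atom_types(mol)
}

# Parse the ATOM/BOND sections of a single-molecule SYBYL MOL2 block.
# (No installed R package reads MOL2; the format is two fixed tables.)
.mol2_to_molgraph <- function(txt, has_coords = FALSE) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  a0 <- match("@<TRIPOS>ATOM", lines)
  b0 <- match("@<TRIPOS>BOND", lines)
  stopifnot(!is.na(a0), !is.na(b0))
  sect_end <- function(start) {
    nxt <- grep("^@<TRIPOS>", lines[(start + 1L):length(lines)])
    if (length(nxt)) start + nxt[1] - 1L else length(lines)
  }
  atom_lines <- lines[(a0 + 1L):sect_end(a0)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  atoms <- data.frame(
    element = vapply(af, function(x) sub("\\..*$", "", x[6]), ""),
    sybyl = vapply(af, function(x) x[6], ""),
    x = vapply(af, function(x) as.numeric(x[3]), 0),
    y = vapply(af, function(x) as.numeric(x[4]), 0),
    z = vapply(af, function(x) as.numeric(x[5]), 0),
    charge = vapply(af, function(x) as.numeric(x[9]), 0),
    stringsAsFactors = FALSE
  )
  bond_lines <- lines[(b0 + 1L):sect_end(b0)]
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
  bonds <- if (length(bond_lines)) {
    bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
    data.frame(
      a1 = vapply(bf, function(x) as.integer(x[2]), 0L),
      a2 = vapply(bf, function(x) as.integer(x[3]), 0L),
      type = vapply(bf, function(x) x[4], ""),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(a1 = integer(), a2 = integer(), type = character())
  }
  n <- nrow(atoms)
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  dist <- igraph::distances(g)
  storage.mode(dist) <- "double"   # Inf for disconnected pairs
  in_ring <- rep(FALSE, n)
  if (nrow(bonds)) {
    bridge <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(bonds)), as.integer(bridge))
    in_ring[unique(c(bonds$a1[ring_edges], bonds$a2[ring_edges]))] <- TRUE
  }
  atoms$in_ring <- in_ring
  atoms$aromatic <- grepl("\\.ar$", atoms$sybyl)
  atoms$hybridization <- .sybyl_hybrid(atoms$sybyl)
  adj <- lapply(seq_len(n), function(i) {
    c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
  })
  atoms$n_attached_H <- vapply(
    adj, function(nb) sum(atoms$element[nb] == "H"), 0L
  )
  masses <- .atomic_masses[atoms$element]
  if (anyNA(masses)) {
    stop("unsupported element(s): ",
         paste(unique(atoms$element[is.na(masses)]), collapse = ", "))
  }
  coords <- NULL
  if (has_coords) coords <- as.matrix(atoms[, c("x", "y", "z")])
  charge <- atoms$charge
  # MOL2 prints charges at 4 decimals; re-centre the rounding residual so
  # the molecular sum equals the net formal charge exactly.
  net <- round(sum(charge))
  charge <- charge + (net - sum(charge)) / length(charge)
  atoms$charge <- charge
  structure(
    list(atoms = atoms, bonds = bonds, adj = adj, dist = dist,
         coords3d = coords, molweight = sum(masses)),
    class = "molgraph"
  )
}

.sybyl_hybrid <- function(sybyl) {
  suf <- sub("^[^.]*\\.?", "", sybyl)
  out <- rep("none", length(sybyl))
  out[suf == "3"] <- "sp3"
  out[suf %in% c("2", "ar", "am", "pl3", "co2")] <- "sp2"
  out[suf == "1"] <- "sp"
  out
}

.n_components <- function(mol) {
  n <- nrow(mol$atoms)
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::components(g)$no
}

#' Default atom-class table
#'
#' Named list of predicates, each taking a `molgraph` and returning one
#' logical per atom. The classes are the pharmacophore categories the
#' descriptor grammar refers to. Every rule is local and structural:
#' \describe{
#'   \item{donor}{N or O bearing at least one hydrogen.}
#'   \item{amide_N}{N single-bonded to a carbon that is double-bonded to O.}
#'   \item{lipophilic}{carbon with no N or O neighbour, any halogen, or S.}
#'   \item{sp2_O}{oxygen with a double bond.}
#'   \item{nonring_O}{oxygen outside any ring.}
#'   \item{ring_C, ring_S}{element in a ring.}
#'   \item{sp3_C, sp2_C}{carbon by hybridisation.}
#' }
#' Supply a modified copy to [assign_atom_types()] to override any rule.
#' @return named list of functions.
#' @export
default_atom_typing <- function() {
  nb_elements <- function(mol, i) mol$atoms$element[mol$adj[[i]]]
  list(
    H = function(mol) mol$atoms$element == "H",
    ring_C = function(mol) mol$atoms$element == "C" & mol$atoms$in_ring,
    ring_S = function(mol) mol$atoms$element == "S" & mol$atoms$in_ring,
    nonring_O = function(mol) mol$atoms$element == "O" & !mol$atoms$in_ring,
    sp3_C = function(mol)
      mol$atoms$element == "C" & mol$atoms$hybridization == "sp3",
    sp2_C = function(mol)
      mol$atoms$element == "C" & mol$atoms$hybridization == "sp2",
    sp2_O = function(mol) {
      dbl <- mol$bonds$type == "2"
      has_dbl <- rep(FALSE, nrow(mol$atoms))
      has_dbl[unique(c(mol$bonds$a1[dbl], mol$bonds$a2[dbl]))] <- TRUE
      mol$atoms$element == "O" & (has_dbl | mol$atoms$sybyl == "O.co2")
    },
    donor = function(mol)
      mol$atoms$element %in% c("N", "O") & mol$atoms$n_attached_H >= 1L,
    amide_N = function(mol) {
      carbonyl_C <- rep(FALSE, nrow(mol$atoms))
      dbl <- mol$bonds$type == "2"
      for (k in which(dbl)) {
        a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
        if (mol$atoms$element[a] == "C" && mol$atoms$element[b] == "O")
          carbonyl_C[a] <- TRUE
        if (mol$atoms$element[b] == "C" && mol$atoms$element[a] == "O")
          carbonyl_C[b] <- TRUE
      }
      vapply(seq_len(nrow(mol$atoms)), function(i) {
        mol$atoms$element[i] == "N" && any(carbonyl_C[mol$adj[[i]]])
      }, NA)
    },
    lipophilic = function(mol) {
      halogen_or_S <- mol$atoms$element %in% c("F", "Cl", "Br", "I", "S")
      plain_C <- mol$atoms$element == "C" &
        !vapply(seq_len(nrow(mol$atoms)), function(i)
          any(nb_elements(mol, i) %in% c("N", "O")), NA)
      plain_C | halogen_or_S
    }
  )
}

#' Assign pharmacophore atom classes to a molecular graph
#'
#' Populates the logical flag matrix the descriptor engine reads. Typing is
#' total (every atom gets every flag evaluated) and idempotent.
#'
#' @param mol a `molgraph`.
#' @param typing a typing table as produced by [default_atom_typing()].
#' @return the graph with a `flags` logical matrix (atoms x classes).
#' @export
assign_atom_types <- function(mol, typing = default_atom_typing()) {
  stopifnot(inherits(mol, "molgraph"))
  flags <- vapply(typing, function(f) f(mol), logical(nrow(mol$atoms)))
  if (nrow(mol$atoms) == 1L) flags <- matrix(flags, nrow = 1L,
                                             dimnames = list(NULL, names(typing)))
  mol$flags <- flags
  mol
}

#' Partial atomic charges
#'
#' Returns the Gasteiger-Marsili partial charges carried by the graph
#' (computed at parse time by iterative partial equalisation of orbital
#' electronegativity). Charges are re-centred so they sum exactly to the
#' net formal charge; they are deterministic for a fixed input structure.
#'
#' @param mol a `molgraph`.
#' @return numeric vector, one charge per atom (explicit-hydrogen graph).
#' @export
partial_charges <- function(mol) {
  stopifnot(inherits(mol, "molgraph"))
  ch <- mol$atoms$charge
  if (anyNA(ch)) stop("partial charges unavailable for this structure")
  ch
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %s (%s): %d atoms (%d heavy), %d bonds, MW %.3f\n",
              x$name, x$smiles, nrow(x$atoms),
              sum(x$atoms$element != "H"), nrow(x$bonds), x$molweight))
  invisible(x)
}

#' Parse many SMILES
#'
#' @param smiles character vector of SMILES.
#' @param names compound identifiers (recycled from seq if missing).
#' @param with_3d embed 3D coordinates.
#' @return list of `molgraph` objects.
#' @export
parse_molecules <- function(smiles, names = NULL, with_3d = FALSE) {
  if (is.null(names)) names <- sprintf("mol%03d", seq_along(smiles))
  mols <- Map(parse_molecule, smiles, names, with_3d = with_3d)
  names(mols) <- names
  mols
}

#' Canonical structure key
#'
#' Canonical SMILES used for duplicate detection during curation. By
#' default stereochemistry is ignored: stereo marks are stripped and the
#' structure re-canonicalised, so enantiomers collapse to one key.
#'
#' @param smiles SMILES string(s).
#' @param ignore_stereo drop stereochemistry before canonicalising.
#' @return character vector of canonical SMILES; NA where unparsable.
#' @export
canonical_key <- function(smiles, ignore_stereo = TRUE) {
  vapply(smiles, function(s) {
    out <- .convert_structure(paste(s, "m"), "SMI", "CAN")
    if (!nzchar(out)) return(NA_character_)
    can <- sub("[\t ].*$", "", trimws(out))
    if (ignore_stereo && grepl("[@/\\\\]", can)) {
      can2 <- gsub("[@/\\\\]", "", can)
      out2 <- .convert_structure(paste(can2, "m"), "SMI", "CAN")
      if (nzchar(out2)) can <- sub("[\t ].*$", "", trimws(out2))
    }
    can
  }, "", USE.NAMES = FALSE)
}

#' Read structures from an SDF (V2000) file
#'
#' Records are converted molecule-by-molecule; coordinates present in the
#' file are honoured (no re-embedding), so geometric descriptors use the
#' supplied geometry.
#'
#' @param path SDF file path.
#' @return list of `molgraph` objects named by the SDF title line.
#' @export
read_sdf_molecules <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  recs <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  mols <- lapply(recs, function(r) {
    title <- strsplit(r, "\n")[[1]][1]
    if (!nzchar(trimws(title))) title <- "mol"
    m2 <- .convert_structure(paste0(r, "\n$$$$\n"), "SDF", "MOL2",
                             .mol2_options(FALSE))
    if (!nzchar(m2)) {
      stop(structure(
        class = c("qsar_parse_error", "error", "condition"),
        list(message = sprintf("cannot parse SDF record '%s'", title),
             call = NULL, smiles = NA_character_)
      ))
    }
    mol <- .mol2_to_molgraph(m2, has_coords = TRUE)
    if (all(abs(mol$coords3d) < 1e-8)) mol$coords3d <- NULL
    mol$name <- trimws(title)
    mol$smiles <- sub("[\t ].*$", "",
                      trimws(.convert_structure(paste0(r, "\n$$$$\n"),
                                                "SDF", "CAN")))
    assign_atom_types(mol)
  })
  names(mols) <- vapply(mols, `[[`, "", "name")
  mols
}

#' Write molecules to an annotated SDF
#'
#' Emits a V2000 SDF with one property block per atom class listing the
#' (1-based) indices of atoms carrying that flag, so typing decisions can
#' be audited in standard viewers.
#'
#' @param mols list of typed `molgraph` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotated_sdf <- function(mols, path) {
  blocks <- vapply(mols, function(mol) {
    sdf <- .convert_structure(paste(mol$smiles, mol$name), "SMI", "SDF",
                              .mol2_options(FALSE))
    sdf <- sub("\\$\\$\\$\\$\\s*$", "", sdf)
    props <- vapply(colnames(mol$flags), function(fl) {
      idx <- which(mol$flags[, fl])
      sprintf(">  <atoms_%s>\n%s\n", fl,
              if (length(idx)) paste(idx, collapse = " ") else "none")
    }, "")
    paste0(sdf, paste(props, collapse = "\n"), "\n$$$$")
  }, "")
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}
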