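test_that("descriptor names parse into the right families and round-trip", {
  cases <- list(
    fNringC6B = list(family = "exact_pair_count", center = "N",
                     target = "ringC", distance = 6L),
    fdonsp3C2B = list(family = "exact_pair_count", center = "don",
                      target = "sp3C", distance = 2L),
    famdNnotringO9B = list(family = "exact_pair_count", center = "amdN",
                           target = "notringO", distance = 9L),
    fringCH3B = list(family = "exact_pair_count", center = "ringC",
                     target = "H", distance = 3L),
    fsp3CamdN4B = list(family = "exact_pair_count", center = "sp3C",
                       target = "amdN", distance = 4L),
    lipo_ringS_8Bc = list(family = "charge_sum_within", center = "ringS",
                          target = "lipo", distance = 8L),
    com_sp2O_4A = list(family = "geometric_count", center = "com",
                       target = "sp2O", distance = 4),
    avg_molweight = list(family = "global_property")
  )
  for (nm in names(cases)) {
    spec <- parse_descriptor(nm)
    expect_equal(spec$name, nm)
    for (f in names(cases[[nm]]))
      expect_equal(spec[[f]], cases[[nm]][[f]],
                   info = paste(nm, f))
  }
  expect_error(parse_descriptor("fFooBar3B"), "atom class")
  expect_error(parse_descriptor("totally_bogus"), "unknown descriptor")
  expect_error(parse_descriptor("fNringC0B"), "distance")
})

test_that("exact pair counts match hand-derived values on probe molecules", {
  methane <- parse_molecule("C")
  expect_equal(count_exact_pairs(methane, "N", "ringC", 6), 0L)

  hex <- parse_molecule("NCCCCCC1CCCCC1")
  expect_equal(count_exact_pairs(hex, "N", "ringC", 6), 1L)

  benzene <- parse_molecule("c1ccccc1")
  expect_equal(count_exact_pairs(benzene, "ringC", "H", 3), 12L)
})

test_that("every toy-suite descriptor equals its brute-force enumeration", {
  suite <- toy_molecule_suite()
  expect_gte(nrow(suite), 12)
  mols <- parse_molecules(suite$smiles, suite$name)
  # classes covered somewhere in the suite
  cover <- Reduce(`+`, lapply(mols, function(m) colSums(m$flags)))
  for (cls in c("ring_S", "amide_N", "donor", "sp2_O", "nonring_O",
                "lipophilic", "H"))
    expect_gt(cover[[cls]], 0)
  golden <- golden_descriptor_values(suite)
  for (i in seq_len(nrow(golden))) {
    got <- evaluate_descriptor(mols[[golden$name[i]]], golden$descriptor[i])
    expect_equal(got, golden$value[i],
                 info = paste(golden$name[i], golden$descriptor[i]))
  }
  # and the package enumerator agrees with the test-local double loop
  for (nm in c("fNringC6B", "fdonsp3C2B", "fringCH3B")) {
    spec <- parse_descriptor(nm)
    for (mol in mols)
      expect_equal(oracle_pair_count(mol, spec$center, spec$target,
                                     spec$distance),
                   evaluate_descriptor(mol, nm))
  }
})

test_that("pair counts summed over all distances enumerate disjoint flag pairs", {
  mol <- parse_molecule("NCCCCCC1CCCCC1")
  diam <- max(mol$dist)
  total <- sum(vapply(seq_len(diam), function(n)
    count_exact_pairs(mol, "N", "ringC", n), 0L))
  n_centers <- sum(mol$atoms$element == "N")
  n_targets <- sum(mol$flags[, "ring_C"])
  expect_equal(total, n_centers * n_targets)
})

test_that("charge sums follow set semantics and the worked examples", {
  benzene <- parse_molecule("c1ccccc1")
  expect_identical(sum_charges_within(benzene, "ringS", "lipo", 8), 0)

  thiophene <- parse_molecule("c1ccsc1")
  got <- sum_charges_within(thiophene, "ringS", "lipo", 8)
  ring_c <- which(thiophene$flags[, "ring_C"])
  expect_equal(got, sum(partial_charges(thiophene)[ring_c]))
  expect_equal(got, oracle_charge_sum(thiophene, "ringS", "lipo", 8))

  # n = 1 reaches only the two alpha carbons; contributing sets nest with n
  near <- sum_charges_within(thiophene, "ringS", "lipo", 1)
  alpha <- which(thiophene$dist[which(thiophene$flags[, "ring_S"]), ] == 1 &
                   thiophene$flags[, "lipophilic"])
  expect_equal(near, sum(partial_charges(thiophene)[alpha]))
  expect_equal(near, oracle_charge_sum(thiophene, "ringS", "lipo", 1))
})

test_that("geometric counts work on embedded structures and fail without geometry", {
  f <- parse_molecule("C=O", "formaldehyde", with_3d = TRUE)
  expect_equal(geometric_count(f, "sp2O", 4), 1L)
  expect_equal(geometric_count(f, "sp2O", 0), 0L)  # empty ball
  expect_equal(evaluate_descriptor(f, "com_sp2O_4A"), 1L)
  ethane <- parse_molecule("CC", with_3d = TRUE)
  expect_equal(evaluate_descriptor(ethane, "com_sp2O_4A"), 0L)
  no3d <- parse_molecule("C=O")
  expect_error(geometric_count(no3d, "sp2O", 4), class = "qsar_no_geometry")
})

test_that("avg_molweight divides by the explicit-hydrogen atom count", {
  expect_equal(avg_molweight(parse_molecule("C")), 16.043 / 5,
               tolerance = 1e-6)
  expect_equal(avg_molweight(parse_molecule("[H][H]")), 1.008,
               tolerance = 1e-6)
  expect_equal(avg_molweight(parse_molecule("OCC")),
               avg_molweight(parse_molecule("CCO")))
})

test_that("compute_matrix is consistent with single-descriptor calls", {
  mols <- parse_molecules(c("OCC", "CC(N)=O", "c1ccsc1"))
  specs <- c("fNringC6B", "fdonsp3C2B", "lipo_ringS_8Bc", "avg_molweight")
  dm <- compute_matrix(mols, specs)
  expect_equal(dim(dm$values), c(3L, 4L))
  for (i in 1:3) for (j in seq_along(specs))
    expect_equal(dm$values[i, j],
                 as.numeric(evaluate_descriptor(mols[[i]], specs[j])))
  # zero specs and duplicated specs
  empty <- compute_matrix(mols, character())
  expect_equal(ncol(empty$values), 0L)
  dup <- compute_matrix(mols, c("fdonsp3C2B", "fdonsp3C2B"))
  expect_equal(dup$values[, 1], dup$values[, 2])
})

test_that("descriptor matrices survive a TSV round trip", {
  dir <- withr::local_tempdir()
  mols <- parse_molecules(c("OCC", "c1ccsc1"))
  dm <- compute_matrix(mols, c("fdonsp3C2B", "lipo_ringS_8Bc"))
  p <- file.path(dir, "dm.tsv")
  write_descriptor_matrix(dm, p)
  back <- read_descriptor_matrix(p)
  expect_equal(back$values, dm$values, tolerance = 1e-12)
  expect_equal(back$compound_ids, dm$compound_ids)
})

test_that("the combinatorial pool has realistic size and parses fully", {
  pool <- descriptor_pool()
  expect_gt(length(pool), 1000)
  expect_lt(length(pool), 2500)
  some <- pool[seq(1, length(pool), by = 97)]
  for (nm in some) expect_s3_class(parse_descriptor(nm), "descriptor_spec")
})
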