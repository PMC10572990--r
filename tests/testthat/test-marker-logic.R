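test_that("Venn partition reproduces hand-worked regions", {
  r <- venn_partition(list(A = c("p1", "p2"), B = "p2"))
  expect_identical(r[["A"]], "p1")
  expect_identical(r[["A&B"]], "p2")
  expect_false("B" %in% names(r))

  r <- venn_partition(list(A = c("a", "b", "c", "d"), B = c("b", "c"),
                           C = c("c", "e")))
  expect_setequal(r[["A"]], c("a", "d"))
  expect_identical(r[["A&B&C"]], "c")
  expect_identical(r[["C"]], "e")
  expect_setequal(r[["A&B"]], "b")

  # three identical sets: only the full intersection survives
  same <- venn_partition(list(X = c("a", "b"), Y = c("a", "b"),
                              Z = c("a", "b")))
  expect_identical(names(same), "X&Y&Z")

  expect_error(venn_partition(list()), class = "lfq_validation_error")
})

test_that("Venn regions are disjoint, cover the union, match brute force", {
  set.seed(31)
  for (n_sets in c(2, 4, 6)) {
    for (rep in 1:3) {
      universe <- sprintf("x%02d", 1:30)
      family <- lapply(seq_len(n_sets), function(i)
        sample(universe, sample(0:20, 1)))
      names(family) <- LETTERS[seq_len(n_sets)]
      regions <- venn_partition(family)
      flat <- unlist(regions, use.names = FALSE)
      expect_identical(anyDuplicated(flat), 0L)        # disjoint
      expect_setequal(flat, unique(unlist(family)))    # coverage
      oracle <- oracle_venn(family)
      expect_setequal(names(regions), names(oracle))
      for (nm in names(oracle)) {
        expect_setequal(regions[[nm]], oracle[[nm]])
      }
      # name order must not matter
      perm <- rev(family)
      r2 <- venn_partition(perm)
      for (nm in names(regions)) {
        parts <- strsplit(nm, "&")[[1]]
        nm2 <- names(r2)[vapply(strsplit(names(r2), "&"), function(p)
          setequal(p, parts), logical(1))]
        expect_setequal(r2[[nm2]], regions[[nm]])
      }
    }
  }
})

test_that("exclusive_proteins extracts the single-set region", {
  fam <- list(A = c("1", "2", "3"), B = c("2", "3", "4"), C = c("3", "5"))
  expect_identical(exclusive_proteins(fam, "A"), "1")
  expect_length(exclusive_proteins(list(A = c("1", "2"),
                                        B = c("1", "2", "3")), "A"), 0)
  expect_identical(exclusive_proteins(list(A = c("7", "8")), "A"),
                   c("7", "8"))
  expect_error(exclusive_proteins(fam, "Z"), class = "lfq_key_error")
})

test_that("combined-insult markers follow the hand-executed set algebra", {
  de <- list(
    "PCPNIC vs CT" = c("m1", "m2", "s1"),
    "PCP vs CT" = "s1",
    "NIC vs CT" = character(0),
    "PCPNIC vs NIC" = c("m1", "m2", "s2"),
    "PCP vs NIC" = "s2",
    "PCPNIC vs PCP" = c("m1", "m3")
  )
  results <- fake_lattice_results(de)
  ms <- pcpnic_markers(results)
  expect_identical(ms$proteins, "m1")
  expect_identical(ms$mode, "exclusivity_refined")
  expect_identical(unname(unlist(ms$directions[1, c("vsCT", "vsNIC",
                                                    "vsPCP")])),
                   c("Up", "Up", "Up"))
  expect_true(ms$directions$consistent)

  # all-empty lattice: empty marker set, not an error
  none <- fake_lattice_results(list())
  expect_length(pcpnic_markers(none)$proteins, 0)

  # a missing arrow is a configuration error naming the comparison
  expect_error(pcpnic_markers(results[1:4]), "PCPNIC vs NIC",
               class = "lfq_config_error")
})

test_that("refined markers are nested inside plain-intersection markers", {
  set.seed(77)
  lat <- comparison_lattice(c("CT", "PCP", "NIC", "PCPNIC"))
  for (rep in 1:10) {
    universe <- sprintf("q%02d", 1:25)
    de <- lapply(setNames(lat$name, lat$name), function(nm)
      sample(universe, sample(0:15, 1)))
    results <- fake_lattice_results(de)
    plain <- group_markers(results, "PCPNIC", "plain_intersection")
    refined <- group_markers(results, "PCPNIC", "exclusivity_refined")
    expect_true(all(refined$proteins %in% plain$proteins))
    # plain intersection equals the brute-force triple intersection
    want <- Reduce(intersect, list(de[["PCPNIC vs CT"]],
                                   de[["PCPNIC vs NIC"]],
                                   de[["PCPNIC vs PCP"]]))
    expect_setequal(plain$proteins, want)
    # markers lie inside every contributing DE set
    for (nm in c("PCPNIC vs CT", "PCPNIC vs NIC", "PCPNIC vs PCP")) {
      expect_true(all(refined$proteins %in% de[[nm]]))
    }
  }
})

test_that("single-insult group markers intersect their three comparisons", {
  de <- list(
    "PCP vs CT" = c("x", "y"),
    "PCP vs NIC" = c("x", "z"),
    "PCPNIC vs PCP" = c("x", "w"),
    "NIC vs CT" = c("y", "z"),
    "PCPNIC vs NIC" = c("w"),
    "PCPNIC vs CT" = c("w", "x")
  )
  results <- fake_lattice_results(de)
  expect_identical(group_markers(results, "PCP")$proteins, "x")

  # pairwise-overlapping but jointly disjoint sets yield no marker
  de2 <- list(
    "NIC vs CT" = c("a", "b"),
    "PCP vs NIC" = c("b", "c"),
    "PCPNIC vs NIC" = c("c", "a"),
    "PCP vs CT" = character(0), "PCPNIC vs CT" = character(0),
    "PCPNIC vs PCP" = character(0)
  )
  results2 <- fake_lattice_results(de2)
  expect_length(group_markers(results2, "NIC")$proteins, 0)
})

test_that("sex-exclusivity fraction counts single-sex DE proteins", {
  male <- fake_lattice_results(list("PCPNIC vs CT" = c("a", "c")))
  female <- fake_lattice_results(list("PCPNIC vs NIC" = c("b", "c")),
                                 sex = "F")
  expect_equal(sex_exclusivity_fraction(male, female), 2 / 3)

  # identical profiles: fraction 0
  same <- fake_lattice_results(list("PCPNIC vs CT" = c("a", "b")))
  same_f <- fake_lattice_results(list("PCPNIC vs CT" = c("a", "b")),
                                 sex = "F")
  expect_equal(sex_exclusivity_fraction(same, same_f), 0)

  # no DE anywhere: NA with a warning
  expect_warning(
    out <- sex_exclusivity_fraction(fake_lattice_results(list()),
                                    fake_lattice_results(list(), sex = "F")),
    "no DE proteins"
  )
  expect_true(is.na(out))
})

test_that("pipeline recovers planted combined-insult markers exactly", {
  config <- synthetic_config(n_proteins = 100, tech_cv = 0.05,
                             bio_cv = 0.05, dropout_midpoint = -Inf,
                             seed = 1)
  planted <- sprintf("P%04d", seq(5, 50, by = 5))
  eff <- planted_effects(planted, "M", "PCPNIC", 4)
  sim <- generate_dataset(config, eff)
  pools <- aggregate_technical(hi3_quantify(
    filter_identifications(sim$peptides)))
  lat <- comparison_lattice(config$groups)
  results <- lapply(seq_len(nrow(lat)), function(i)
    pairwise_compare(pools, "M", lat$focal[i], lat$reference[i]))
  ms <- pcpnic_markers(results)
  expect_setequal(ms$proteins, planted)
  expect_setequal(sim$truth$expected_markers$M$PCPNIC, planted)
  expect_true(all(ms$directions$vsCT == "Up"))

  # planting the same effect in PCP removes it from the refined set
  sim2 <- generate_dataset(config, planted_effects(
    c(planted, planted[1]), "M", c(rep("PCPNIC", length(planted)), "PCP"),
    4))
  pools2 <- aggregate_technical(hi3_quantify(
    filter_identifications(sim2$peptides)))
  results2 <- lapply(seq_len(nrow(lat)), function(i)
    pairwise_compare(pools2, "M", lat$focal[i], lat$reference[i]))
  ms2 <- pcpnic_markers(results2)
  expect_false(planted[1] %in% ms2$proteins)
  expect_setequal(ms2$proteins, setdiff(planted, planted[1]))
})
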