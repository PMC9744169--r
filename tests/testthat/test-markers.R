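test_that("band matrix CSV round-trips and rejects malformed input", {
  m <- random_bm(8, 6, miss = 0.1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_band_matrix(m, path)
  m2 <- read_band_matrix(path, "M", "P")
  expect_identical(m2$calls, m$calls)
  expect_identical(m2$primer_map, m$primer_map)

  expect_error(read_band_matrix(path, "M", "nope"), "nope")
  # non-binary cell
  txt <- readLines(path)
  txt[3] <- sub("0", "7", txt[3])
  writeLines(txt, path)
  expect_error(read_band_matrix(path, "M", "P"), "non-\\{0,1,NA\\}")
})

test_that("band_matrix enforces its invariants", {
  calls <- rbind(M = c(1L, NA), P = c(0L, NA), o1 = c(1L, NA))
  colnames(calls) <- c("a", "b")
  expect_error(bm(calls), "no non-missing call.*b")
  calls2 <- rbind(M = c(1L, 1L), o1 = c(1L, 0L))
  colnames(calls2) <- c("a", "b")
  expect_error(bm(calls2), "father|'P'")
  calls3 <- rbind(M = 1L, P = 0L, o1 = 2L)
  colnames(calls3) <- "a"
  expect_error(bm(calls3), "0, 1 or NA")
})

test_that("characteristic bands follow the parental definitions", {
  calls <- rbind(M = c(1L, 0L, 1L), P = c(1L, 1L, 0L), o1 = c(1L, 1L, 0L))
  colnames(calls) <- c("a", "b", "c")
  b <- detect_characteristic_bands(bm(calls))
  expect_identical(b$paternal_only[[1]], "b")
  expect_identical(b$maternal_only[[1]], "c")
  expect_identical(b$shared[[1]], "a")
  expect_identical(b$MF1, 1L)
  expect_identical(b$FF1, 1L)

  # identical parents: all sets empty
  calls2 <- rbind(M = c(1L, 0L), P = c(1L, 0L), o1 = c(1L, 1L))
  colnames(calls2) <- c("a", "b")
  b2 <- detect_characteristic_bands(bm(calls2))
  expect_length(b2$paternal_only[[1]], 0)
  expect_length(b2$maternal_only[[1]], 0)

  # loci with a missing parent call are excluded and reported
  calls3 <- rbind(M = c(NA, 1L), P = c(1L, 0L), o1 = c(1L, 1L))
  colnames(calls3) <- c("a", "b")
  expect_message(b3 <- detect_characteristic_bands(bm(calls3)), "missing parent")
  expect_identical(attr(b3, "excluded"), "a")
  expect_identical(b3$maternal_only[[1]], "b")
})

test_that("characteristic bands match the brute-force set comprehension", {
  for (seed in 1:5) {
    m <- random_bm(6, 50, miss = 0.05, seed = seed)
    suppressMessages(b <- detect_characteristic_bands(m))
    o <- oracle_bands(m)
    expect_identical(sort(unlist(b$paternal_only)), o$paternal)
    expect_identical(sort(unlist(b$maternal_only)), o$maternal)
    expect_identical(sort(unlist(b$shared)), o$shared)
  }
})

test_that("offspring classification and purity follow the female-marker-type rule", {
  # 10 offspring: 7 carry a paternal band, 2 carry none (scored), 1 all-missing
  calls <- rbind(M = c(0L, 0L, 1L), P = c(1L, 1L, 1L))
  calls <- rbind(calls,
                 matrix(c(rep(c(1L, 0L, 1L), 7),
                          rep(c(0L, 0L, 1L), 2),
                          c(NA, NA, 1L)), ncol = 3, byrow = TRUE))
  rownames(calls) <- c("M", "P", sprintf("o%02d", 1:10))
  colnames(calls) <- c("a", "b", "c")
  cl <- classify_offspring(bm(calls))
  expect_identical(sum(cl$calls$call == "true_hybrid"), 7L)
  expect_identical(sum(cl$calls$call == "maternal_type"), 2L)
  expect_identical(sum(cl$calls$call == "unresolved"), 1L)
  expect_identical(cl$n_tested, 9L)
  expect_equal(cl$purity, 100 * (9 - 2) / 9)
  expect_identical(cl$false_hybrid_ids, c("o08", "o09"))
  # exact complement identity
  expect_equal(cl$purity + 100 * 2 / 9, 100)

  # every offspring carries a band -> purity 100, no false hybrids
  calls2 <- calls[c("M", "P", sprintf("o%02d", 1:7)), ]
  cl2 <- classify_offspring(bm(calls2))
  expect_equal(cl2$purity, 100)
  expect_length(cl2$false_hybrid_ids, 0)

  # no paternal characteristic band anywhere -> classification impossible
  calls3 <- rbind(M = c(1L, 1L), P = c(1L, 1L), o1 = c(1L, 0L))
  colnames(calls3) <- c("a", "b")
  expect_error(classify_offspring(bm(calls3)), "classification impossible")

  # stricter calling: min_paternal_bands = 2 demotes single-band carriers
  cl3 <- classify_offspring(bm(calls), min_paternal_bands = 2)
  expect_identical(sum(cl3$calls$call == "true_hybrid"), 0L)
})

test_that("purity recovers the selfing rate exactly with a homozygous paternal band", {
  parents <- parent_genotypes(rep("p1", 3), c("a", "b", "c"),
                              mother_genotype = c(0L, 2L, 1L),
                              father_genotype = c(2L, 0L, 1L))
  cfg <- simulation_config(1500, "F1", selfing_rate = 0.06, seed = 13)
  sim <- simulate_offspring(parents, cfg)
  cl <- classify_offspring(sim$matrix)
  realized <- mean(sim$truth$truth == "maternal_self")
  expect_equal(cl$purity, 100 * (1 - realized))
  # and the calls agree with the truth labels one-for-one
  expect_identical(cl$calls$call == "maternal_type",
                   sim$truth$truth == "maternal_self")
})

test_that("maternal-type fraction matches s + (1-s)/2 with one heterozygous paternal band", {
  parents <- parent_genotypes(rep("p1", 2), c("a", "b"),
                              mother_genotype = c(0L, 2L),
                              father_genotype = c(1L, 2L))
  s <- 0.1
  n <- 5000
  sim <- simulate_offspring(parents, simulation_config(n, "F1", selfing_rate = s, seed = 21))
  cl <- classify_offspring(sim$matrix)
  p_expect <- s + (1 - s) / 2
  frac <- mean(cl$calls$call == "maternal_type")
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(frac - p_expect), 3 * se)
})

test_that("allele frequencies under both estimators", {
  calls <- rbind(M = c(1L, 0L, 1L), P = c(1L, 0L, 0L),
                 matrix(c(1L, 0L, 1L,
                          1L, 0L, 0L,
                          1L, 0L, 1L,
                          1L, 0L, 0L,
                          1L, 0L, 1L,
                          1L, 0L, 0L,
                          1L, 0L, 1L,
                          1L, 0L, 0L), ncol = 3, byrow = TRUE))
  rownames(calls) <- c("M", "P", sprintf("o%d", 1:8))
  colnames(calls) <- c("fix1", "fix0", "seg")
  m <- bm(calls)
  f_ph <- allele_frequencies(m, "phenotypic")
  expect_equal(f_ph$p[f_ph$locus_id == "fix1"], 1)
  expect_equal(f_ph$p[f_ph$locus_id == "fix0"], 0)
  expect_equal(f_ph$p[f_ph$locus_id == "seg"], 5 / 10)  # hand count incl. parents

  f_hw <- allele_frequencies(m, "hwe_dominant")
  expect_equal(f_hw$p[f_hw$locus_id == "fix1"], 1)
  expect_equal(f_hw$q[f_hw$locus_id == "seg"], sqrt(0.5))
  # closed form: absent frequency 0.25 -> q = 0.5
  calls2 <- rbind(M = 1L, P = 1L, o1 = 1L, o2 = 0L)
  colnames(calls2) <- "x"
  f2 <- allele_frequencies(bm(calls2), "hwe_dominant")
  expect_equal(f2$q, 0.5)
  expect_equal(f2$p, 0.5)
})

test_that("diversity statistics: closed forms and identities", {
  # locus with p = q = 0.5 -> ne = 2, h = 0.5, I = ln 2; monomorphic -> 1,1,0,0
  calls <- rbind(M = c(1L, 1L), P = c(0L, 1L), o1 = c(1L, 1L), o2 = c(0L, 1L))
  colnames(calls) <- c("half", "mono")
  d <- diversity_stats(bm(calls))
  pl <- attr(d, "per_locus")
  expect_equal(pl$ne[pl$locus_id == "half"], 2)
  expect_equal(pl$h[pl$locus_id == "half"], 0.5)
  expect_equal(pl$i[pl$locus_id == "half"], log(2))
  expect_equal(unlist(pl[pl$locus_id == "mono", c("na", "ne", "h", "i")],
                      use.names = FALSE),
               c(1, 1, 0, 0))

  # identities on simulated panels: na = 1 + ppb/100, h = 1 - 1/ne, ne <= na
  for (seed in 1:3) {
    parents <- simulate_parents(3, 8, 0.7, seed = seed)
    sim <- simulate_offspring(parents,
                              simulation_config(40, "F1", selfing_rate = 0.05,
                                                seed = seed))
    ds <- diversity_stats(sim$matrix)
    primer_rows <- ds[ds$primer_id != "Mean", ]
    expect_equal(primer_rows$na_mean, 1 + primer_rows$ppb / 100)
    expect_true(all(primer_rows$ne_mean <= primer_rows$na_mean + 1e-12))
    pl <- attr(ds, "per_locus")
    expect_equal(pl$h, 1 - 1 / pl$ne)
    # panel Mean row averages the per-primer means
    expect_equal(ds$na_mean[ds$primer_id == "Mean"], mean(primer_rows$na_mean))
  }
})

test_that("similarity coefficients: identity, disjoint and brute-force oracle", {
  calls <- rbind(M = c(1L, 1L, 0L, 0L), P = c(0L, 0L, 1L, 1L),
                 o1 = c(1L, 1L, 0L, 0L))
  colnames(calls) <- letters[1:4]
  for (coef in c("simple_matching", "dice", "jaccard")) {
    s <- similarity_matrix(bm(calls), coef)
    expect_equal(unname(s["M", "o1"]), 1)      # identical profiles
    expect_equal(unname(s["M", "P"]), 0)       # fully disjoint
    expect_true(isSymmetric(unclass(s)))
    expect_equal(unname(diag(s)), rep(1, 3))
  }

  m <- random_bm(5, 20, miss = 0.1, seed = 8)
  for (coef in c("simple_matching", "dice", "jaccard")) {
    s <- similarity_matrix(m, coef)
    ids <- rownames(m$calls)
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(unname(s[i, j]),
                   oracle_similarity(m$calls[i, ], m$calls[j, ], coef),
                   info = sprintf("%s pair %s-%s", coef, ids[i], ids[j]))
    }
  }

  # pair with no shared scored locus errors, naming the pair
  calls2 <- rbind(M = c(1L, NA), P = c(NA, 1L), o1 = c(1L, 1L))
  colnames(calls2) <- c("a", "b")
  expect_error(similarity_matrix(bm(calls2)), "M, P|P, M")
})

test_that("similarity summary reports parental ranges and extreme pairs", {
  calls <- rbind(M = c(1L, 1L, 0L, 0L), P = c(0L, 0L, 1L, 1L),
                 o1 = c(0L, 0L, 1L, 1L),   # identical to father
                 o2 = c(1L, 1L, 1L, 0L),
                 o3 = c(1L, 1L, 0L, 0L))   # identical to mother
  colnames(calls) <- letters[1:4]
  s <- similarity_matrix(bm(calls))
  su <- similarity_summary(s)
  expect_equal(su$progeny_father$max, 1)
  expect_identical(su$progeny_father$max_id, "o1")
  expect_equal(su$progeny_mother$max, 1)
  expect_equal(su$parent_parent, unname(s["M", "P"]))

  # exhaustive check of ranges on the 3 offspring
  off <- c("o1", "o2", "o3")
  expect_equal(su$progeny_father$min, min(s[off, "P"]))
  expect_equal(su$progeny_mother$min, min(s[off, "M"]))
  pair_vals <- c(s["o1", "o2"], s["o1", "o3"], s["o2", "o3"])
  expect_equal(su$overall$min, min(pair_vals))
  expect_equal(su$overall$max, max(pair_vals))
})
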