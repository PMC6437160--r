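test_that("enrichment_score matches its closed-form examples", {
  m <- matrix(5, 4, 6, dimnames = list(paste0("p", 1:4), NULL))
  grp <- c("skeletal_muscle", "skeletal_muscle", rep("other", 4))
  sc <- enrichment_score(m, grp)
  expect_equal(sc$score, rep(0, 4))   # constant matrix
  # target max 9999, overall median 0 -> log10(1e4) - log10(1) = 4
  m2 <- matrix(0, 1, 11, dimnames = list("p1", NULL))
  g2 <- c(rep("skeletal_muscle", 2), rep("other", 9))
  m2[1, 1] <- 9999
  expect_equal(enrichment_score(m2, g2)$score, 4)
  expect_error(enrichment_score(m, rep("other", 6)), "empty")
  expect_error(enrichment_score(m, rep("skeletal_muscle", 6)), "proper subset")
  mneg <- m; mneg[1, 1] <- -1
  expect_error(enrichment_score(mneg, grp), "non-negative")
})

test_that("enrichment score is monotone in the target max and stable to
           non-max target additions", {
  base <- matrix(rep(c(10, 5, 5, 5, 5, 5), each = 1), 1, 6,
                 dimnames = list("p1", NULL))
  grp <- c("skeletal_muscle", rep("other", 5))
  s1 <- enrichment_score(base, grp)$score
  # adding a target sample below the max leaves the score's max term fixed
  base2 <- cbind(base, 7)
  grp2 <- c(grp, "skeletal_muscle")
  s2 <- enrichment_score(base2, grp2)$score
  expect_equal(log10(11) - s1, log10(stats::median(base[1, ]) + 1))
  expect_equal(s2, log10(11) - log10(stats::median(base2[1, ]) + 1))
  # raising the target max raises the score
  base3 <- base; base3[1, 1] <- 100
  expect_gt(enrichment_score(base3, grp)$score, s1)
})

test_that("select_candidates partitions with a strict threshold", {
  res <- data.frame(promoter = c("a", "b", "c", "d"),
                    score = c(3.5, 3.0, 2.9, 4.2))
  sel <- select_candidates(res, threshold = 3,
                           known_disease_genes = c("a", "zz"))
  expect_setequal(sel$enriched, c("a", "d"))   # score exactly 3.0 excluded
  expect_identical(sel$known, "a")
  expect_identical(sel$novel, "d")
  # empty known set: novel = enriched
  sel2 <- select_candidates(res, threshold = 3)
  expect_setequal(sel2$novel, sel2$enriched)
})

test_that("a 82/31/51 style partition arises by construction", {
  ids <- sprintf("p%04d", 1:82)
  m <- gen_expression_matrix(n_promoters = 500, n_samples = 80,
                             enriched_ids = ids, fold = 5e3, seed = 8)
  sc <- enrichment_score(m)
  sel <- select_candidates(sc, threshold = 3,
                           known_disease_genes = sprintf("p%04d", 1:31))
  expect_identical(unname(sel$counts),
                   c(82L, 31L, 51L))
})

test_that("LOD identities: theta = 0.5 gives 0; single individual gives 0", {
  ped <- ped_trio()
  g <- rbind(c(1, 2), c(1, 1), c(1, 1))
  expect_identical(lod_single_marker(ped, g, theta = 0.5), 0)
  solo <- pedigree(id = "x", affected = 1)
  gs <- matrix(c(1, 2), 1)
  for (th in c(0, 0.1, 0.3)) {
    expect_equal(lod_single_marker(solo, gs, theta = th), 0, tolerance = 1e-12)
  }
})

test_that("m phase-known non-recombinant meioses give m*log10(2)", {
  mdl <- disease_model(disease_freq = 1e-4, penetrance = c(0, 1, 1))
  for (m in c(3, 10)) {
    ped <- ped_phase_known(m)
    expect_equal(lod_single_marker(ped, model = mdl, theta = 0),
                 m * log10(2), tolerance = 1e-9)
  }
})

test_that("peeling equals brute-force enumeration on <= 6-member pedigrees", {
  mdl <- disease_model()
  peds <- list(trio = ped_trio(),
               nuclear4 = ped_nuclear(2),
               nuclear5 = ped_nuclear(3),
               threegen = ped_three_gen())
  genos <- list(
    trio = rbind(c(1, 2), c(1, 1), c(1, 1)),
    nuclear4 = rbind(c(1, 2), c(2, 2), c(1, 2), c(2, 2)),
    nuclear5 = rbind(c(1, 2), c(1, 2), c(1, 1), c(1, 2), c(2, 2)),
    threegen = rbind(c(1, 1), c(2, 2), c(1, 2), c(2, 2), c(1, 2), c(2, 2))
  )
  for (nm in names(peds)) {
    for (th in c(0, 0.1, 0.25)) {
      got <- lod_single_marker(peds[[nm]], genos[[nm]], model = mdl,
                               marker_freqs = c(0.4, 0.6), theta = th)
      want <- brute_lod(peds[[nm]], genos[[nm]], mdl, c(0.4, 0.6), th)
      expect_equal(got, want, tolerance = 1e-9,
                   label = sprintf("peeling LOD (%s, theta=%.2f)", nm, th))
    }
  }
})

test_that("peeling matches brute force with missing data and 3 alleles", {
  mdl <- disease_model()
  ped <- ped_nuclear(2)
  g <- rbind(c(1, 3), c(2, 2), c(NA, NA), c(2, 3))
  fr <- c(0.2, 0.5, 0.3)
  for (th in c(0.05, 0.4)) {
    expect_equal(lod_single_marker(ped, g, model = mdl, marker_freqs = fr,
                                   theta = th),
                 brute_lod(ped, g, mdl, fr, th), tolerance = 1e-9)
  }
})

test_that("invalid pedigrees and genotypes are rejected informatively", {
  expect_error(pedigree(id = c("a", "b"), father = c("b", "a"),
                        mother = c("b", "a")), "cycle")
  expect_error(pedigree(id = c("a", "b"), father = c(NA, "zz"),
                        mother = c(NA, "a")), "missing parent")
  expect_error(pedigree(id = c("a", "b"), father = c(NA, "a"),
                        mother = c(NA, NA)), "one parent")
  # Mendelian inconsistency names the trio
  ped <- ped_trio()
  bad <- rbind(c(1, 1), c(1, 1), c(1, 2))
  expect_error(lod_single_marker(ped, bad, theta = 0.1), "child 'c'")
  # marriage loop (two sibs marry two sibs' offspring... simplest: child of
  # related parents)
  loop <- pedigree(id = c("f", "m", "s1", "s2", "gc"),
                   father = c(NA, NA, "f", "f", "s1"),
                   mother = c(NA, NA, "m", "m", "s2"))
  gl <- matrix(1L, 5, 2)
  expect_error(lod_single_marker(loop, gl, theta = 0.1), "loop")
})

test_that("max_lod recovers linkage and stays near zero when unlinked", {
  mdl <- disease_model(0.05, c(0, 1, 1))
  ped <- ped_nuclear(8, aff = rep(NA, 10))
  # seed picked so the simulated family is informative (affected founder
  # heterozygous at both loci), mirroring an ascertained disease pedigree
  linked <- gen_pedigree_genotypes(ped, marker_freqs = c(0.5, 0.5),
                                   theta_true = 0, model = mdl, seed = 14)
  ml <- max_lod(linked, model = mdl)
  expect_identical(ml$theta_hat, 0)
  expect_gt(ml$lod_max, 1)
  expect_identical(ml$lod_max, max(ml$lod))
  # unlinked: LOD_max stays small
  lods <- vapply(1:10, function(s) {
    unl <- gen_pedigree_genotypes(ped, theta_true = 0.5, model = mdl,
                                  seed = 100 + s)
    max_lod(unl, model = mdl)$lod_max
  }, numeric(1))
  expect_lt(stats::median(lods), 0.3)
})
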