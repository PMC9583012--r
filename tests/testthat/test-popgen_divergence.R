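## Small helper: genotype matrix straight from a call matrix.
gm_from_calls <- function(calls, species) {
  sites <- data.frame(chromosome = "1X", position = seq_len(ncol(calls)),
                      site_id = paste0("1X:", seq_len(ncol(calls))))
  genotype_matrix(calls, sites, species)
}

test_that("Fst hits its fixed-difference and no-differentiation endpoints", {
  sp <- setNames(rep(c("A", "B"), each = 3), paste0("x", 1:6))
  fixed <- gm_from_calls(matrix(rep(c("C", "C", "C", "T", "T", "T"), 2),
                                nrow = 6, dimnames = list(names(sp), NULL)), sp)
  for (est in c("nei_gst", "weir_cockerham")) {
    f <- pairwise_fst(fixed, "A", "B", est)
    expect_equal(f$fst, 1)
  }
  ident <- gm_from_calls(matrix(rep(c("C", "C", "T", "C", "C", "T"), 3),
                                nrow = 6, dimnames = list(names(sp), NULL)), sp)
  for (est in c("nei_gst", "weir_cockerham")) {
    f <- pairwise_fst(ident, "A", "B", est)
    expect_equal(f$fst, 0)
  }
  # Ht = 0 everywhere -> undefined
  mono <- gm_from_calls(matrix("G", 6, 2, dimnames = list(names(sp), NULL)), sp)
  expect_error(pairwise_fst(mono, "A", "B"), "undefined at every locus")
})

test_that("Nei Gst equals hand-computed Ht/Hs arithmetic on a toy matrix", {
  # species A: alleles C,C,C,T (p_C = 3/4); species B: C,T,T,T (p_C = 1/4)
  sp <- setNames(rep(c("A", "B"), each = 4), paste0("x", 1:8))
  col1 <- c("C", "C", "C", "T", "C", "T", "T", "T")
  # locus 2: A all C, B half/half
  col2 <- c("C", "C", "C", "C", "C", "C", "T", "T")
  gm <- gm_from_calls(matrix(c(col1, col2), nrow = 8,
                             dimnames = list(names(sp), NULL)), sp)
  f <- pairwise_fst(gm, "A", "B", "nei_gst")
  # locus 1: Hs = mean(2*3/4*1/4, 2*1/4*3/4) = 0.375; pooled p = 0.5,
  # Ht = 0.5
  hs1 <- 0.375; ht1 <- 0.5
  # locus 2: Hs = mean(0, 0.5) = 0.25; pooled p = 0.75, Ht = 0.375
  hs2 <- 0.25; ht2 <- 0.375
  expect_equal(f$per_locus[["1X:1"]], (ht1 - hs1) / ht1)
  expect_equal(f$per_locus[["1X:2"]], (ht2 - hs2) / ht2)
  expect_equal(f$fst, ((ht1 - hs1) + (ht2 - hs2)) / (ht1 + ht2))
  expect_equal(f$fst_mean_of_ratios,
               mean(c((ht1 - hs1) / ht1, (ht2 - hs2) / ht2)))
})

test_that("Fst is invariant to allele relabeling and accession order", {
  set.seed(191)
  gm <- random_genotype(200, missing_rate = 0.02, het_rate = 0.02)
  f <- pairwise_fst(gm, "A", "B")
  # relabel alleles A<->C, G<->T (a bijection on the base alphabet)
  relab <- c(A = "C", C = "A", G = "T", T = "G", "." = ".",
             R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K")
  gm2 <- gm; gm2$calls[] <- relab[gm$calls]
  expect_equal(pairwise_fst(gm2, "A", "B")$fst, f$fst)
  perm <- sample(gm$accessions)
  gm3 <- genotype_matrix(gm$calls[perm, ], gm$sites, gm$species)
  expect_equal(pairwise_fst(gm3, "A", "B")$fst, f$fst)
})

test_that("the two estimators agree on balanced designs at many loci", {
  sim <- simulate_genotype_matrix(n_diagnostic = 0, n_background = 500,
                                  species = c("A", "B"),
                                  accessions_per_species = c(20L, 20L),
                                  background_fst = 0.1, seed = 201)
  g <- pairwise_fst(sim$genotype, "A", "B", "nei_gst")
  w <- pairwise_fst(sim$genotype, "A", "B", "weir_cockerham")
  expect_lt(abs(g$fst - w$fst), 0.02)
})

test_that("multi-locus Fst decreases with simulated migration", {
  mean_fst <- function(m) {
    mean(sapply(1:50, function(r) {
      sim <- simulate_genotype_matrix(n_diagnostic = 0, n_background = 80,
                                      species = c("A", "B"),
                                      accessions_per_species = c(8L, 8L),
                                      m = m, seed = 5000 + 13 * r + round(m * 1e4))
      pairwise_fst(sim$genotype, "A", "B")$fst
    }))
  }
  f0 <- mean_fst(0); f3 <- mean_fst(0.3); f6 <- mean_fst(0.6)
  expect_gt(f0, f3)
  expect_gt(f3, f6)
})

test_that("the island-model identity converts Fst to Nm", {
  expect_equal(fst_migration_consistency(0.2), 1.0)
  expect_equal(fst_migration_consistency(0.5), 0.25)
  expect_true(is.na(fst_migration_consistency(0)))
  expect_true(is.na(fst_migration_consistency(1)))
  fs <- seq(0.05, 0.95, by = 0.05)
  nm <- vapply(fs, fst_migration_consistency, 0)
  expect_true(all(diff(nm) < 0))
  # accepts an fst_result
  sp <- setNames(rep(c("A", "B"), each = 3), paste0("x", 1:6))
  gm <- gm_from_calls(matrix(c("C", "C", "T", "T", "T", "T",
                               "C", "C", "C", "T", "C", "T"), nrow = 6,
                             dimnames = list(names(sp), NULL)), sp)
  f <- pairwise_fst(gm, "A", "B")
  expect_equal(fst_migration_consistency(f),
               (1 - f$fst) / (4 * f$fst))
})

test_that("the all-pairs Fst table covers every species pair", {
  fx <- aegilops_snp_fixture()
  tab <- fst_matrix(fx$genotype)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$fst >= 0 & tab$fst <= 1))
})
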