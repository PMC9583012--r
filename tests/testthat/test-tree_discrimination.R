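test_that("NJ recovers additive quartets and three-taxon stars exactly", {
  # quartet from a known tree with internal edge 0.05:
  # ((a:0.1,b:0.2):0.05,c:0.15,d:0.25)
  lab <- c("a", "b", "c", "d")
  D <- matrix(0, 4, 4, dimnames = list(lab, lab))
  D["a", "b"] <- D["b", "a"] <- 0.3
  D["a", "c"] <- D["c", "a"] <- 0.3
  D["a", "d"] <- D["d", "a"] <- 0.4
  D["b", "c"] <- D["c", "b"] <- 0.4
  D["b", "d"] <- D["d", "b"] <- 0.5
  D["c", "d"] <- D["d", "c"] <- 0.4
  tr <- nj_tree(list(accessions = lab, d = D))
  expect_equal(cophenetic(tr)[lab, lab], D, tolerance = 1e-12)
  expect_true(oracle_monophyletic(tr, c("a", "b")))

  # three taxa resolve by the three-point formulas
  D3 <- matrix(c(0, 0.3, 0.4, 0.3, 0, 0.5, 0.4, 0.5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(list(accessions = c("x", "y", "z"), d = D3))
  expect_equal(cophenetic(tr3)[c("x", "y", "z"), c("x", "y", "z")], D3,
               tolerance = 1e-12)

  # ultrametric 2-cluster matrix: clusters come out as sister groups
  lab6 <- c("p1", "p2", "p3", "q1", "q2", "q3")
  D6 <- matrix(0.5, 6, 6, dimnames = list(lab6, lab6))
  D6[1:3, 1:3] <- 0.1; D6[4:6, 4:6] <- 0.1; diag(D6) <- 0
  tr6 <- nj_tree(list(accessions = lab6, d = D6))
  expect_true(oracle_monophyletic(tr6, c("p1", "p2", "p3")))
})

test_that("NJ is consistent on random additive matrices", {
  set.seed(123)
  for (rep in 1:10) {
    rt <- ape::rtree(8)
    rt$edge.length <- runif(nrow(rt$edge), 0.05, 0.5)
    D <- cophenetic(rt)
    tr <- nj_tree(list(accessions = rownames(D), d = D))
    expect_equal(cophenetic(tr)[rownames(D), rownames(D)], D,
                 tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(rt), tr), 0, ignore_attr = TRUE)
  }
})

test_that("NJ validates input and names undefined pairs", {
  lab <- c("a", "b", "c", "d")
  D <- matrix(0.2, 4, 4, dimnames = list(lab, lab)); diag(D) <- 0
  D["a", "c"] <- D["c", "a"] <- NA
  expect_error(nj_tree(list(accessions = lab, d = D)), "'a' and 'c'")
  expect_error(nj_tree(list(accessions = lab[1:2], d = D[1:2, 1:2])),
               "at least 3")
})

test_that("monophyly verdicts match the ape rooted-clade oracle", {
  # hand-built verdicts
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_equal(monophyly_rate(good, sp)$rate, 100)
  expect_equal(monophyly_rate(bad, sp)$rate, 0)
  expect_error(monophyly_rate(good, sp[1:3]), "species label")

  # random 20-leaf trees vs the independent rooted-clade oracle
  set.seed(131)
  for (rep in 1:20) {
    tr <- ape::rtree(20)
    sp20 <- setNames(sample(paste0("s", 1:5), 20, replace = TRUE),
                     tr$tip.label)
    score <- monophyly_rate(tr, sp20)
    for (k in seq_len(nrow(score$per_species))) {
      s <- score$per_species$species[k]
      expect_equal(score$per_species$monophyletic[k],
                   oracle_monophyletic(tr, names(sp20)[sp20 == s]),
                   info = paste("species", s, "rep", rep))
    }
  }
})

test_that("monophyly is invariant to rerooting and leaf permutation", {
  set.seed(141)
  cfg <- species_sim_config(n_species = 5, accessions_per_species = 3,
                            locus_lengths = c(l = 400),
                            intra_divergence = 0.004,
                            inter_divergence = 0.03, seed = 142)
  aln <- simulate_barcode_alignments(cfg)$l
  tr <- nj_tree(distance_matrix(aln))
  base <- monophyly_rate(tr, aln$species)
  for (out in sample(tr$tip.label, 4)) {
    rr <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    rescore <- monophyly_rate(rr, aln$species)
    expect_equal(rescore$rate, base$rate)
  }
  # singletons count as monophyletic and are flagged
  spx <- aln$species
  spx[1] <- "lonely"
  sc <- monophyly_rate(tr, spx)
  row <- sc$per_species[sc$per_species$species == "lonely", ]
  expect_true(row$monophyletic && row$singleton)
  expect_false(is.na(sc$rate_multi))
})

test_that("section clustering reduces to species monophyly on identical labels", {
  set.seed(151)
  cfg <- species_sim_config(n_species = 4, accessions_per_species = 3,
                            locus_lengths = c(l = 300),
                            intra_divergence = 0.003,
                            inter_divergence = 0.03, seed = 152)
  aln <- simulate_barcode_alignments(cfg)$l
  tr <- nj_tree(distance_matrix(aln))
  expect_equal(section_clustering(tr, aln$species)$rate,
               monophyly_rate(tr, aln$species)$rate)
  # a section split across two clades is not monophyletic
  sp <- c(a1 = "S1", a2 = "S1", b1 = "S2", b2 = "S2")
  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_equal(section_clustering(bad, sp)$rate, 0)
})

test_that("bootstrap supports are deterministic and bounded", {
  set.seed(161)
  cfg <- species_sim_config(n_species = 4, accessions_per_species = 3,
                            locus_lengths = c(l = 500),
                            intra_divergence = 0.005,
                            inter_divergence = 0.05, seed = 162)
  aln <- simulate_barcode_alignments(cfg)$l
  b1 <- bootstrap_support(aln, replicates = 25, seed = 9)
  b2 <- bootstrap_support(aln, replicates = 25, seed = 9)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 100))
  # one replicate yields supports in {0, 100}
  b3 <- bootstrap_support(aln, replicates = 1, seed = 10)
  expect_true(all(b3$support %in% c(0, 100)))
  expect_error(bootstrap_support(aln, replicates = 5), "seed")
})
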