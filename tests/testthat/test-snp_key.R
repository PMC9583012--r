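test_that("site statistics recover the printed major-allele frequencies", {
  fx <- aegilops_snp_fixture()
  st <- site_stats(fx$genotype)
  # row 1 spot check: 11 C vs 3 G of 14
  expect_equal(st$major_allele[1], "C")
  expect_equal(round_half_up(st$major_allele_freq[1], 5), 0.78571)
  # all 30 printed frequencies and allele lists
  expect_equal(round_half_up(st$major_allele_freq, 5),
               fx$printed$major_allele_freq)
  expect_equal(st$alleles, fx$printed$alleles)
  expect_true(all(st$missing_frac == 0) && all(st$het_frac == 0))
})

test_that("site statistics equal a brute-force tally on random matrices", {
  set.seed(171)
  for (rep in 1:20) {
    gm <- random_genotype(50)
    st <- site_stats(gm)
    for (j in sample(50, 10)) {
      col <- gm$calls[, j]
      hom <- col[col %in% c("A", "C", "G", "T")]
      if (length(hom) == 0L) {
        expect_true(is.na(st$major_allele_freq[j]))
      } else {
        expect_equal(st$major_allele_freq[j], max(table(hom)) / length(hom))
        expect_equal(st$missing_frac[j], mean(col == "."))
      }
    }
  }
  # monomorphic site has frequency 1
  mono <- random_genotype(1, missing_rate = 0, het_rate = 0)
  mono$calls[, 1] <- "T"
  expect_equal(site_stats(mono)$major_allele_freq, 1)
})

test_that("the site filter applies all three thresholds and is idempotent", {
  set.seed(181)
  gm <- random_genotype(1000, missing_rate = 0.04, het_rate = 0.1)
  f <- filter_sites(gm)
  keep <- oracle_filter_keep(gm, 0.95, 0.05, 0.20)
  expect_equal(f$sites$site_id, gm$sites$site_id[keep])
  expect_equal(f$accessions, gm$accessions)
  f2 <- filter_sites(f)
  expect_identical(f2$calls, f$calls)

  # monomorphic and high-missingness sites are removed
  gm2 <- random_genotype(2, missing_rate = 0, het_rate = 0)
  gm2$calls[, 1] <- "A"
  gm2$calls[1:2, 2] <- "."
  f3 <- filter_sites(gm2, max_missing = 0.05)
  expect_equal(ncol(f3$calls), 0L)
  expect_error(filter_sites(gm2, max_major_af = 1.5), "\\[0, 1\\]")
})

test_that("diagnostic screening applies the allele-set disjointness rule", {
  fx <- aegilops_snp_fixture()
  key <- screen_diagnostic(fx$genotype)
  expect_equal(nrow(key$sites), 30L)

  # row 1 pattern: juvenalis holds the private G
  expect_equal(key$sites$diagnoses[1], "Ae. juvenalis")
  # row 4 pattern: columnaris {A, C} overlaps biuncialis {C}, juvenalis
  # {G} stays private
  expect_equal(key$sites$diagnoses[key$sites$site_id == "1D:438741637"],
               "Ae. juvenalis")
  # row 6 pattern: biuncialis {G} is private against {T, A}
  expect_equal(key$sites$diagnoses[key$sites$site_id == "2D:154402884"],
               "Ae. biuncialis")

  # a site where every species shares an allele is not retained
  gm <- fx$genotype
  gm$calls[, 1] <- "T"
  gm$calls[1, 1] <- "C"
  key2 <- screen_diagnostic(gm)
  expect_false("1D:170914803" %in% key2$sites$site_id)

  # invariance to accession and species order
  perm <- sample(fx$genotype$accessions)
  gmp <- genotype_matrix(fx$genotype$calls[perm, ], fx$genotype$sites,
                         fx$genotype$species)
  keyp <- screen_diagnostic(gmp, species = rev(key$species))
  expect_equal(sort(keyp$sites$site_id), sort(key$sites$site_id))
  expect_equal(
    sort(strsplit(keyp$sites$diagnoses[keyp$sites$site_id == "1D:170914803"], ",")[[1]]),
    sort(strsplit(key$sites$diagnoses[key$sites$site_id == "1D:170914803"], ",")[[1]]))
})

test_that("heterozygous calls expand to both alleles before disjointness", {
  sp <- setNames(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2"))
  sites <- data.frame(chromosome = "1X", position = 1:2,
                      site_id = c("1X:1", "1X:2"))
  # site 1: a-species het R = {A,G} overlaps B's {G}: not diagnostic
  # site 2: het Y = {C,T} within species A only: diagnostic for A
  calls <- matrix(c("R", "A", "G", "G",
                    "Y", "C", "G", "G"), nrow = 4,
                  dimnames = list(names(sp), NULL))
  gm <- genotype_matrix(calls, sites, sp)
  key <- screen_diagnostic(gm)
  expect_equal(key$sites$site_id, "1X:2")
  expect_equal(key$sites$diagnoses, "A,B")
})

test_that("classification votes over the key recover known samples", {
  fx <- aegilops_snp_fixture()
  key <- screen_diagnostic(fx$genotype)
  sids <- colnames(fx$genotype$calls)
  for (acc in c("W-43", "W-2", "W-9")) {
    res <- classify_sample(key, setNames(fx$genotype$calls[acc, ], sids))
    expect_equal(res$verdict, unname(fx$genotype$species[acc]),
                 info = acc)
  }
  # all-missing input is unclassified
  res <- classify_sample(key, setNames(rep(".", length(sids)), sids))
  expect_equal(res$verdict, "unclassified")
  expect_true(all(res$votes == 0))
  # an exact 50/50 vote split is a tie -> unclassified
  half <- fx$genotype$calls["W-43", ]
  juv_sites <- sids[grepl("juvenalis", key$sites$diagnoses)]
  col_sites <- sids[grepl("columnaris", key$sites$diagnoses)]
  probe <- setNames(rep(".", length(sids)), sids)
  probe[juv_sites[1:2]] <- fx$genotype$calls["W-43", juv_sites[1:2]]
  probe[col_sites[1:2]] <- fx$genotype$calls["W-9", col_sites[1:2]]
  res2 <- classify_sample(key, probe)
  expect_equal(res2$verdict, "unclassified")
  # unknown sites are ignored with a warning
  expect_warning(classify_sample(key, c(`9Z:1` = "A")), "not in the key")
})

test_that("screening recovers exactly the planted diagnostic sites", {
  for (r in 1:5) {
    sim <- simulate_genotype_matrix(n_diagnostic = 12, n_background = 200,
                                    n_monomorphic = 20, seed = 300 + r)
    key <- screen_diagnostic(sim$genotype)
    planted <- sim$truth$site_id[sim$truth$class == "diagnostic"]
    expect_equal(sort(key$sites$site_id), sort(planted))
    # the diagnosed species matches the planted truth
    expect_equal(
      key$sites$diagnoses[match(planted, key$sites$site_id)],
      sim$truth$diagnosed_species[sim$truth$class == "diagnostic"])
  }
})

test_that("the serialized key reproduces the printed table layout", {
  fx <- aegilops_snp_fixture()
  key <- screen_diagnostic(fx$genotype)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diagnostic_key(key, path)
  out <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  ref <- utils::read.delim(
    system.file("extdata", "aegilops_snp_key_table.tsv",
                package = "barcodekey"),
    colClasses = "character", check.names = FALSE)
  expect_equal(out$major_allele_freq, ref$major_allele_freq)
  expect_equal(out$position, ref$position)
  acc <- fx$genotype$accessions
  expect_equal(out[, acc], ref[, acc])
})
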