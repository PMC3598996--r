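make_gm <- function(codes, animals, snps) {
  matrix(as.integer(codes), length(animals), length(snps),
         dimnames = list(animals, snps), byrow = TRUE)
}

test_that("chromosome filter removes exactly the excluded-chromosome SNP and keeps the map sorted", {
  map <- marker_map(paste0("s", 1:6), c("1", "1", "Y", "2", "Y", "Y"),
                    c(10L, 20L, 5L, 15L, 30L, 50L))
  gm <- hwe_genotypes(8L, stats::setNames(rep(0.4, 6), map$snp_id), seed = 1L)
  out <- filter_chromosomes(gm, map)
  expect_setequal(out$removed_snps, map$snp_id[map$chrom == "Y"])
  expect_equal(ncol(out$genotypes), 3L)
  expect_true(keyimpute:::map_is_sorted(out$map))
  ## no excluded chromosomes present: identity
  clean <- filter_chromosomes(out$genotypes, out$map)
  expect_identical(clean$genotypes, out$genotypes)
  expect_length(clean$removed_snps, 0L)
})

test_that("duplicate-position survivor has the best call rate and is deterministic", {
  map <- marker_map(c("a", "b", "c"), "1", c(100L, 100L, 200L))
  gm <- make_gm(c(0, NA, 1,
                  1, 1, 2,
                  2, 0, 0), c("x1", "x2", "x3"), c("a", "b", "c"))
  out <- drop_duplicate_positions(gm, map)
  expect_equal(out$removed_snps, "b")          # "a" is complete, "b" is not
  rerun <- drop_duplicate_positions(gm, map)
  expect_identical(out, rerun)
  ## tie on call rate falls back to the lexicographically smaller id
  gm2 <- make_gm(rep(1, 9), c("x1", "x2", "x3"), c("a", "b", "c"))
  expect_equal(drop_duplicate_positions(gm2, map)$removed_snps, "b")
  none <- drop_duplicate_positions(gm2[, c("a", "c")], map[map$snp_id != "b", ])
  expect_length(none$removed_snps, 0L)
})

test_that("call-rate filter removes animals first, then SNP, with strict thresholds", {
  snps <- sprintf("s%02d", 1:100)
  map <- marker_map(snps, "1", seq(100L, by = 100L, length.out = 100L))
  gm <- hwe_genotypes(20L, stats::setNames(rep(0.5, 100), snps), seed = 2L)
  complete <- filter_missingness(gm, map)
  expect_identical(complete$genotypes, gm)
  ## one animal with 6% missing is dropped at the default 5% threshold
  gm2 <- gm
  gm2["an001", 1:6] <- NA
  out <- filter_missingness(gm2, map)
  expect_equal(out$removed_animals, "an001")
  ## exactly 5% missing is retained (strict >)
  gm3 <- gm
  gm3["an002", 1:5] <- NA
  expect_length(filter_missingness(gm3, map)$removed_animals, 0L)
})

test_that("animal-then-SNP filter order matches the documented output on a crafted fixture", {
  ## 5 animals x 5 SNP; animal a1 misses 3/5 SNP; SNP s1 is missing only
  ## in a1, so once a1 is gone s1 is complete and must survive.
  snps <- paste0("s", 1:5)
  map <- marker_map(snps, "1", (1:5) * 100L)
  gm <- matrix(1L, 5, 5, dimnames = list(paste0("a", 1:5), snps))
  gm["a1", c("s1", "s2", "s3")] <- NA
  cfg <- qc_config(max_animal_missing = 0.5, max_snp_missing = 0.1)
  out <- filter_missingness(gm, map, cfg)
  expect_equal(out$removed_animals, "a1")
  expect_length(out$removed_snps, 0L)
  ## SNP-first ordering would instead have removed s1..s3 and kept a1
  snp_first_removed <- colnames(gm)[colMeans(is.na(gm)) > 0.1]
  expect_equal(snp_first_removed, c("s1", "s2", "s3"))
})

test_that("Hardy-Weinberg chi-square reproduces closed forms and the direct formula", {
  perfect <- hwe_test(25L, 50L, 25L)
  expect_equal(perfect$chisq, 0)
  expect_equal(perfect$p_value, 1)
  ## complete heterozygote deficit: chi-square equals n
  deficit <- hwe_test(50L, 0L, 50L)
  expect_equal(deficit$chisq, 100)
  expect_equal(deficit$p_value, stats::pchisq(100, 1, lower.tail = FALSE))
  ## independent hand computation of the three terms for (50, 30, 20)
  n <- 100
  p_b <- (2 * 20 + 30) / 200
  e <- c(n * (1 - p_b)^2, 2 * n * p_b * (1 - p_b), n * p_b^2)
  o <- c(50, 30, 20)
  expect_equal(hwe_test(50L, 30L, 20L)$chisq, sum((o - e)^2 / e))
  ## monomorphic convention and allele-label symmetry
  expect_equal(hwe_test(60L, 0L, 0L)$p_value, 1)
  set.seed(3)
  for (i in 1:20) {
    cnt <- as.integer(stats::rmultinom(1, 80, c(0.3, 0.5, 0.2)))
    a <- hwe_test(cnt[1], cnt[2], cnt[3])
    b <- hwe_test(cnt[3], cnt[2], cnt[1])
    expect_equal(a$p_value, b$p_value)
    expect_true(a$p_value >= 0 && a$p_value <= 1)
  }
})

test_that("MAF filter is strict at 1% and exclusion counts match a brute-force recount", {
  n_an <- 500L
  snps <- sprintf("s%02d", 1:52)
  gm <- matrix(0L, n_an, 52, dimnames = list(sprintf("a%03d", 1:n_an), snps))
  gm[1:10, "s01"] <- 1L     # allele_b frequency exactly 0.01 -> retained
  gm[1:9, "s02"] <- 1L      # 0.009 -> removed
  set.seed(4)
  for (j in 3:52) gm[, j] <- stats::rbinom(n_an, 2L, stats::runif(1, 0.02, 0.5))
  map <- marker_map(snps, "1", (1:52) * 1000L)
  out <- filter_maf_hwe(gm, map)
  expect_true("s02" %in% out$removed_maf)
  expect_false("s01" %in% out$removed_maf)
  ## brute-force recount on the 50-SNP random block
  p <- colMeans(gm, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  expect_setequal(out$removed_maf, names(maf)[maf < 0.01])
})

test_that("Mendelian errors are opposite homozygotes only and both genotypes become missing", {
  ped <- pedigree(c("SIRE", "DAM", "OFF"), c("0", "0", "SIRE"),
                  c("0", "0", "DAM"))
  snps <- paste0("s", 1:4)
  gm <- make_gm(c(0, 2, 1, 2,
                  2, 0, 1, 2), c("SIRE", "OFF"), snps)
  out <- mendelian_check(gm, ped)
  expect_equal(out$errors$n_errors, 2L)        # s1 (0 vs 2) and s2 (2 vs 0)
  expect_true(all(is.na(out$genotypes[, c("s1", "s2")])))
  expect_equal(out$genotypes["SIRE", "s3"], 1L)
  expect_equal(out$genotypes["OFF", "s4"], 2L) # 2 vs 2 compatible
  ## heterozygous sire is never in conflict
  gm2 <- make_gm(c(1, 1, 1, 1,
                   0, 1, 2, 0), c("SIRE", "OFF"), snps)
  expect_equal(mendelian_check(gm2, ped)$n_errors, 0L)
})

test_that("Mendelian error counts equal an exhaustive loop over pairs and SNP", {
  pop <- tiny_population(seed = 19L)
  gm <- pop$truth$genotypes
  set.seed(20)
  flip <- sample(length(gm), 400L)
  gm[flip] <- 2L - gm[flip]                    # plant conflicts
  out <- mendelian_check(gm, pop$pedigree)
  ped <- pop$pedigree
  ids <- rownames(gm)
  expected <- 0L
  for (i in seq_len(nrow(ped))) {
    if (ped$sire[i] == "0" || !(ped$sire[i] %in% ids) ||
        !(ped$animal[i] %in% ids)) next
    for (j in seq_len(ncol(gm))) {
      gs <- gm[ped$sire[i], j]
      go <- gm[ped$animal[i], j]
      if (!is.na(gs) && !is.na(go) && abs(gs - go) == 2L) {
        expected <- expected + 1L
      }
    }
  }
  expect_equal(out$n_errors, expected)
})

test_that("each QC filter is idempotent", {
  pop <- tiny_population(seed = 23L, missing_rate = 0.02,
                         geno_error_rate = 0.01)
  gm <- pop$genotypes
  map <- pop$map
  once <- filter_chromosomes(gm, map)
  expect_identical(filter_chromosomes(once$genotypes, once$map)$genotypes,
                   once$genotypes)
  once <- drop_duplicate_positions(gm, map)
  expect_identical(drop_duplicate_positions(once$genotypes, once$map)$genotypes,
                   once$genotypes)
  once <- filter_missingness(gm, map)
  twice <- filter_missingness(once$genotypes, once$map)
  expect_identical(twice$genotypes, once$genotypes)
  expect_length(twice$removed_animals, 0L)
  once <- filter_maf_hwe(gm, map)
  twice <- filter_maf_hwe(once$genotypes, once$map)
  expect_identical(twice$genotypes, once$genotypes)
  once <- mendelian_check(gm, pop$pedigree)
  twice <- mendelian_check(once$genotypes, pop$pedigree)
  expect_identical(twice$genotypes, once$genotypes)
  expect_equal(twice$n_errors, 0L)
})

test_that("QC report exclusion counts are consistent with the final dimensions", {
  pop <- tiny_population(seed = 29L, missing_rate = 0.02,
                         geno_error_rate = 0.01)
  res <- run_qc(pop$genotypes, pop$map, pop$pedigree,
                screen_relationships = FALSE)
  expect_equal(ncol(res$genotypes),
               ncol(pop$genotypes) - sum(res$report$snps_removed))
  expect_equal(nrow(res$genotypes),
               nrow(pop$genotypes) - sum(res$report$animals_removed))
  expect_equal(nrow(res$map), ncol(res$genotypes))
})

test_that("relationship screen flags a planted sample swap and nothing when G equals A", {
  cfg <- sim_config(n_sires = 6L, offspring_per_sire = 12L,
                    n_generations = 2L, n_chromosomes = 2L,
                    n_snps_per_chrom = 400L, n_founder_haplotypes = 30L,
                    missing_rate = 0, geno_error_rate = 0, seed = 37L)
  pop <- simulate_population(cfg)
  ped <- pop$pedigree
  A <- build_nrm(ped)
  ids <- rownames(pop$genotypes)
  A <- A[ids, ids]
  expect_length(relationship_discrepancy_screen(A, A, ped), 0L)

  ## swap the genotype rows of two offspring from different sire families
  off <- ped[!is_founder(ped), ]
  fam <- split(off$animal, off$sire)
  a1 <- intersect(fam[[1]], ids)[1]
  a2 <- intersect(fam[[4]], ids)[1]
  gm <- pop$genotypes
  tmp <- gm[a1, ]
  gm[a1, ] <- gm[a2, ]
  gm[a2, ] <- tmp
  G <- build_grm(gm)
  flagged <- relationship_discrepancy_screen(A, G, ped)
  expect_true(all(c(a1, a2) %in% flagged))
})

test_that("animals without first-degree relatives cannot be flagged", {
  ped <- pedigree(c("LONER", "P1", "P2", "KID"),
                  c("0", "0", "0", "P1"), c("0", "0", "0", "P2"))
  A <- build_nrm(ped)
  G <- A
  G["LONER", "KID"] <- G["KID", "LONER"] <- 0.9   # absurd, but pairless
  expect_false("LONER" %in% relationship_discrepancy_screen(A, G, ped))
})
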