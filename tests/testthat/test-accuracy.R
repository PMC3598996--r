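## small handmade scenario over explicit matrices
cells_scenario <- function(truth, imputed, masked = colnames(truth)) {
  structure(list(reference = character(0), validation = rownames(truth),
                 masked = masked,
                 retained = setdiff(colnames(truth), masked)),
            class = "imputation_scenario")
}

test_that("concordance scores follow the per-cell allele-credit definition", {
  truth <- matrix(c(0L, 1L, 2L, 1L), 1, 4,
                  dimnames = list("v", paste0("s", 1:4)))
  same <- concordance(truth, truth, cells_scenario(truth, truth))
  expect_equal(same$correct_alleles, 1)
  expect_equal(same$correct_genotypes, 1)
  imp <- matrix(c(2L, 2L, 2L, 1L), 1, 4,
                dimnames = dimnames(truth))
  cc <- concordance(truth, imp, cells_scenario(truth, imp))
  ## cells contribute 0, 1/2, 1, 1 correct-allele credits
  expect_equal(cc$correct_alleles, mean(c(0, 0.5, 1, 1)))
  expect_equal(cc$correct_genotypes, 0.5)
})

test_that("concordance equals a brute-force cell loop on a 10 x 50 fixture", {
  set.seed(31)
  truth <- matrix(sample(0:2, 500, TRUE), 10, 50,
                  dimnames = list(sprintf("v%02d", 1:10),
                                  sprintf("s%02d", 1:50)))
  imp <- truth
  imp[sample(500, 120)] <- sample(0:2, 120, TRUE)
  masked <- sprintf("s%02d", 11:50)
  sc <- cells_scenario(truth, imp, masked)
  cc <- concordance(truth, imp, sc)
  alleles <- geno <- 0
  n <- 0
  for (a in rownames(truth)) {
    for (s in masked) {
      alleles <- alleles + (2 - abs(truth[a, s] - imp[a, s])) / 2
      geno <- geno + (truth[a, s] == imp[a, s])
      n <- n + 1
    }
  }
  expect_equal(cc$correct_alleles, alleles / n)
  expect_equal(cc$correct_genotypes, geno / n)
  expect_gte(cc$correct_alleles, cc$correct_genotypes)
})

test_that("genotype concordance never exceeds allelic concordance", {
  set.seed(32)
  for (k in 1:10) {
    truth <- matrix(sample(0:2, 200, TRUE), 5, 40,
                    dimnames = list(paste0("v", 1:5), paste0("s", 1:40)))
    imp <- matrix(sample(0:2, 200, TRUE), 5, 40, dimnames = dimnames(truth))
    cc <- concordance(truth, imp, cells_scenario(truth, imp))
    expect_gte(cc$correct_alleles, cc$correct_genotypes)
  }
})

test_that("true-imputed correlation matches the direct Pearson formula", {
  truth <- matrix(rep(c(0L, 1L, 2L, 1L), 2), 2, 4, byrow = TRUE,
                  dimnames = list(c("v1", "v2"), paste0("s", 1:4)))
  perfect <- r_tg_ig(truth, truth, cells_scenario(truth, truth))
  expect_equal(perfect$r, c(1, 1))
  flipped <- 2L - truth
  expect_equal(r_tg_ig(truth, flipped, cells_scenario(truth, flipped))$r,
               c(-1, -1))
  imp <- matrix(rep(c(0L, 1L, 1L, 1L), 2), 2, 4, byrow = TRUE,
                dimnames = dimnames(truth))
  got <- r_tg_ig(truth, imp, cells_scenario(truth, imp))$r[1]
  x <- c(0, 1, 2, 1)
  y <- c(0, 1, 1, 1)
  n <- 4
  hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(got, hand)
})

test_that("zero-variance groups are excluded and counted", {
  truth <- matrix(c(1L, 1L, 1L, 1L,
                    0L, 1L, 2L, 1L), 2, 4, byrow = TRUE,
                  dimnames = list(c("flat", "ok"), paste0("s", 1:4)))
  imp <- matrix(c(0L, 1L, 2L, 1L,
                  0L, 1L, 2L, 1L), 2, 4, byrow = TRUE,
                dimnames = dimnames(truth))
  out <- r_tg_ig(truth, imp, cells_scenario(truth, imp))
  expect_true(is.na(out$r[out$animal == "flat"]))
  map <- marker_map(paste0("s", 1:4), "1", (1:4) * 100L)
  byc <- r_tg_ig(truth, imp, cells_scenario(truth, imp),
                 by = "chromosome", map = map)
  expect_equal(byc$n_animals_excluded, 1L)
  expect_equal(byc$r_mean_animal, 1)
})

test_that("per-chromosome summary equals the mean of per-animal correlations", {
  pop <- tiny_population(seed = 113L)
  ids <- rownames(pop$genotypes)
  ref <- ids[1:8]
  val <- setdiff(ids, ref)
  truth <- pop$truth$genotypes[ids, pop$map$snp_id]
  sc <- make_scenario(truth, pop$map, ref, val)
  set.seed(33)
  imp <- truth
  flip <- sample(length(imp), 2000L)
  imp[flip] <- sample(0:2, 2000L, TRUE)
  byc <- r_tg_ig(truth, imp, sc$scenario, by = "chromosome", map = pop$map)
  for (ch in byc$chrom) {
    snps <- intersect(pop$map$snp_id[pop$map$chrom == ch],
                      sc$scenario$masked)
    per <- vapply(val, function(a) stats::cor(truth[a, snps], imp[a, snps]),
                  numeric(1))
    expect_equal(byc$r_mean_animal[byc$chrom == ch],
                 mean(per, na.rm = TRUE))
  }
})

test_that("all metrics are invariant to a simultaneous allele-label flip", {
  set.seed(34)
  truth <- matrix(sample(0:2, 300, TRUE), 6, 50,
                  dimnames = list(paste0("v", 1:6), sprintf("s%02d", 1:50)))
  imp <- truth
  imp[sample(300, 60)] <- sample(0:2, 60, TRUE)
  sc <- cells_scenario(truth, imp)
  a <- concordance(truth, imp, sc)
  b <- concordance(2L - truth, 2L - imp, sc)
  expect_equal(a, b)
  expect_equal(r_tg_ig(truth, imp, sc)$r, r_tg_ig(2L - truth, 2L - imp, sc)$r)
})

test_that("the LOESS curve is constant at one for perfect imputation and stays within the data range", {
  set.seed(35)
  freqs <- stats::setNames(stats::runif(60, 0.1, 0.9), sprintf("s%02d", 1:60))
  truth <- hwe_genotypes(40L, freqs, prefix = "v", seed = 36L)
  sc <- cells_scenario(truth, truth)
  out <- frequency_stratified_accuracy(truth, truth, sc, freqs)
  expect_true(all(abs(out$curve$concordance - 1) < 1e-8))
  ## noisy imputation: grid predictions stay inside the observed range
  imp <- truth
  imp[sample(length(imp), 400L)] <- sample(0:2, 400L, TRUE)
  out2 <- frequency_stratified_accuracy(truth, imp, sc, freqs)
  expect_true(all(out2$curve$concordance >=
                    min(out2$points$concordance) - 1e-12))
  expect_true(all(out2$curve$concordance <=
                    max(out2$points$concordance) + 1e-12))
})

test_that("the frequency-fill curve shows the rare-allele failure analytically expected of a modal filler", {
  ## per-allele concordance of the modal filler is 1 for the major and 0
  ## for the minor allele, so the fitted curve must be near 0 below and
  ## near 1 above the 0.5 boundary
  set.seed(37)
  freqs <- stats::setNames(stats::runif(150, 0.05, 0.95),
                           sprintf("s%03d", 1:150))
  truth <- hwe_genotypes(60L, freqs, prefix = "v", seed = 38L)
  obs_freq <- allele_frequency(truth)
  imp <- truth
  imp[] <- NA_integer_
  imp <- frequency_fill(imp, obs_freq)
  sc <- cells_scenario(truth, imp)
  out <- frequency_stratified_accuracy(truth, imp, sc, obs_freq)
  low <- out$curve$frequency < 0.35
  high <- out$curve$frequency > 0.65
  expect_lt(mean(out$curve$concordance[low]), 0.15)
  expect_gt(mean(out$curve$concordance[high]), 0.85)
})

test_that("accuracy joins relatives profiles without losing animals", {
  per_animal <- data.frame(animal = paste0("v", 1:6),
                           r = c(0.9, 0.95, 0.8, NA, 0.99, 0.85),
                           n_cells = 100L)
  profile <- data.frame(animal = paste0("v", 1:6),
                        n_r_ge_0.50 = c(1L, 2L, 0L, 0L, 1L, 0L),
                        n_r_0.25_0.50 = 0L, n_r_0.125_0.25 = 0L,
                        n_r_0.0625_0.125 = 0L,
                        n_close = c(1L, 2L, 0L, 0L, 3L, 0L),
                        has_close = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  out <- accuracy_vs_relatives(per_animal, profile)
  expect_equal(nrow(out$per_animal), 6L)
  expect_equal(as.character(out$summary$close_relatives), c("0", "1", "2+"))
  expect_equal(out$summary$n_animals, c(3L, 1L, 2L))
  expect_equal(out$summary$mean_r[out$summary$close_relatives == "1"], 0.9)
  ## all animals in one bin still yields a well-formed summary
  one_bin <- accuracy_vs_relatives(per_animal,
                                   transform(profile, n_close = 0L))
  expect_equal(one_bin$summary$n_animals, c(6L, 0L, 0L))
})

test_that("animals with a close reference relative are imputed more accurately", {
  close_r <- numeric(0)
  far_r <- numeric(0)
  for (k in 1:5) {
    ## reference drawn from two sire families only, so the other families
    ## provide validation animals without any close reference relative
    pop <- tiny_population(seed = 400L + k, n_sires = 8L,
                           n_generations = 1L,
                           n_founder_haplotypes = 60L)
    ids <- rownames(pop$genotypes)
    A <- build_nrm(pop$pedigree)[ids, ids]
    fams <- pop$pedigree[!is_founder(pop$pedigree), ]
    ref <- fams$animal[fams$sire %in% c("S001", "S002")][1:8]
    val <- setdiff(ids, ref)
    truth <- pop$truth$genotypes[ids, pop$map$snp_id]
    sc <- make_scenario(truth, pop$map, ref, val)
    res <- hmm_impute(sc$scenario, sc$genotypes, pop$map,
                      haps_matrix(pop$truth$haplotypes$h1,
                                  pop$truth$haplotypes$h2, ref,
                                  pop$map$snp_id),
                      haps_matrix(pop$truth$haplotypes$h1,
                                  pop$truth$haplotypes$h2, val,
                                  pop$map$snp_id))
    per <- r_tg_ig(truth, res$genotypes, sc$scenario, dosage = res$dosage)
    prof <- relatives_profile(A, ref, val)
    joined <- accuracy_vs_relatives(per, prof)$per_animal
    close_r <- c(close_r, joined$r[joined$n_close > 0])
    far_r <- c(far_r, joined$r[joined$n_close == 0])
  }
  expect_gte(mean(close_r, na.rm = TRUE), mean(far_r, na.rm = TRUE))
})
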