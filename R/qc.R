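#' Quality-control configuration
#'
#' Thresholds for the QC cascade applied to dense SNP genotypes. All
#' comparisons are strict: an animal is dropped when its missing fraction
#' exceeds `max_animal_missing`, a SNP when its minor allele frequency is
#' strictly below `min_maf`, and so on.
#'
#' @param max_snp_missing maximum tolerated missing fraction per SNP.
#' @param max_animal_missing maximum tolerated missing fraction per animal.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_alpha p-value threshold for the Hardy-Weinberg test.
#' @param excluded_chromosomes chromosome labels removed outright
#'   (sex/mitochondrial/unplaced markers).
#' @param discrepancy_threshold maximum tolerated |pedigree - genomic|
#'   relationship difference among first-degree relatives before an animal
#'   is flagged.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_snp_missing = 0.05,
                      max_animal_missing = 0.05,
                      min_maf = 0.01,
                      hwe_alpha = 1e-6,
                      excluded_chromosomes = c("Y", "MT", "unknown"),
                      discrepancy_threshold = 0.15) {
  cfg <- list(max_snp_missing = max_snp_missing,
              max_animal_missing = max_animal_missing,
              min_maf = min_maf,
              hwe_alpha = hwe_alpha,
              excluded_chromosomes = as.character(excluded_chromosomes),
              discrepancy_threshold = discrepancy_threshold)
  for (f in c("max_snp_missing", "max_animal_missing", "min_maf",
              "hwe_alpha", "discrepancy_threshold")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop(f, " must lie in (0, 1)")
  }
  class(cfg) <- "qc_config"
  cfg
}

#' Remove SNP on excluded chromosomes
#'
#' @param gm genotype matrix.
#' @param map aligned [marker_map()].
#' @param cfg a [qc_config()].
#' @return list(genotypes, map, removed_snps).
#' @export
filter_chromosomes <- function(gm, map, cfg = qc_config()) {
  drop <- map$chrom %in% cfg$excluded_chromosomes
  removed <- map$snp_id[drop]
  map <- map[!drop, , drop = FALSE]
  rownames(map) <- NULL
  list(genotypes = gm[, map$snp_id, drop = FALSE], map = map,
       removed_snps = removed)
}

#' Drop duplicated (chromosome, position) SNP
#'
#' Of each set of SNP sharing a position, the one with the highest call
#' rate survives; ties are broken by lexicographically smaller id, making
#' the survivor deterministic.
#'
#' @inheritParams filter_chromosomes
#' @return list(genotypes, map, removed_snps).
#' @export
drop_duplicate_positions <- function(gm, map) {
  key <- paste(map$chrom, map$pos, sep = ":")
  call_rate <- colMeans(!is.na(gm[, map$snp_id, drop = FALSE]))
  keep <- unlist(lapply(split(seq_len(nrow(map)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    cr <- call_rate[map$snp_id[idx]]
    idx[order(-cr, map$snp_id[idx])[1]]
  }), use.names = FALSE)
  keep <- sort(keep)
  removed <- map$snp_id[-keep]
  map <- map[keep, , drop = FALSE]
  rownames(map) <- NULL
  list(genotypes = gm[, map$snp_id, drop = FALSE], map = map,
       removed_snps = removed)
}

#' Filter on call rate: animals first, then SNP
#'
#' Animals whose missing fraction strictly exceeds `max_animal_missing`
#' are removed first; SNP missingness is then recomputed on the surviving
#' animals and SNP strictly above `max_snp_missing` are removed.
#'
#' @inheritParams filter_chromosomes
#' @return list(genotypes, map, removed_animals, removed_snps).
#' @export
filter_missingness <- function(gm, map, cfg = qc_config()) {
  miss_a <- rowMeans(is.na(gm))
  removed_animals <- rownames(gm)[miss_a > cfg$max_animal_missing]
  gm <- gm[setdiff(rownames(gm), removed_animals), , drop = FALSE]
  miss_s <- colMeans(is.na(gm))
  removed_snps <- colnames(gm)[miss_s > cfg$max_snp_missing]
  gm <- gm[, setdiff(colnames(gm), removed_snps), drop = FALSE]
  map <- map[map$snp_id %in% colnames(gm), , drop = FALSE]
  rownames(map) <- NULL
  list(genotypes = gm, map = map, removed_animals = removed_animals,
       removed_snps = removed_snps)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against expected proportions p^2, 2pq, q^2 computed from the observed
#' allele frequency. Monomorphic SNP return p = 1 by convention. The test
#' is invariant to swapping the two allele labels.
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectors allowed): homozygous for
#'   allele a, heterozygous, homozygous for allele b.
#' @return data.frame with `chisq` and `p_value`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (any(n <= 0)) stop("at least one genotype observation required")
  p <- (2 * n_bb + n_ab) / (2 * n)      # frequency of allele b
  q <- 1 - p
  e_aa <- n * q^2
  e_ab <- 2 * n * p * q
  e_bb <- n * p^2
  chisq <- ifelse(p <= 0 | p >= 1, 0,
                  (n_aa - e_aa)^2 / e_aa +
                  (n_ab - e_ab)^2 / e_ab +
                  (n_bb - e_bb)^2 / e_bb)
  pv <- ifelse(p <= 0 | p >= 1, 1,
               stats::pchisq(chisq, df = 1, lower.tail = FALSE))
  data.frame(chisq = chisq, p_value = pv)
}

genotype_counts <- function(gm) {
  cbind(n_aa = colSums(gm == 0L, na.rm = TRUE),
        n_ab = colSums(gm == 1L, na.rm = TRUE),
        n_bb = colSums(gm == 2L, na.rm = TRUE))
}

#' Allele-b frequencies from a genotype matrix
#'
#' @param gm genotype matrix; missing genotypes are ignored.
#' @return Named numeric vector of allele_b frequencies per SNP.
#' @export
allele_frequency <- function(gm) {
  colMeans(gm, na.rm = TRUE) / 2
}

#' Filter SNP on minor allele frequency, then Hardy-Weinberg
#'
#' SNP with MAF strictly below `min_maf` (computed on non-missing
#' genotypes) are removed first; the HWE test is then applied to the
#' survivors and SNP with p strictly below `hwe_alpha` are removed.
#'
#' @inheritParams filter_chromosomes
#' @return list(genotypes, map, removed_maf, removed_hwe).
#' @export
filter_maf_hwe <- function(gm, map, cfg = qc_config()) {
  p <- allele_frequency(gm)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  removed_maf <- colnames(gm)[maf < cfg$min_maf]
  gm <- gm[, setdiff(colnames(gm), removed_maf), drop = FALSE]
  cnt <- genotype_counts(gm)
  informative <- rowSums(cnt) > 0
  hw <- rep(1, ncol(gm))
  if (any(informative)) {
    hw[informative] <- hwe_test(cnt[informative, 1], cnt[informative, 2],
                                cnt[informative, 3])$p_value
  }
  removed_hwe <- colnames(gm)[hw < cfg$hwe_alpha]
  gm <- gm[, setdiff(colnames(gm), removed_hwe), drop = FALSE]
  map <- map[map$snp_id %in% colnames(gm), , drop = FALSE]
  rownames(map) <- NULL
  list(genotypes = gm, map = map, removed_maf = removed_maf,
       removed_hwe = removed_hwe)
}

#' Check sire-offspring pairs for Mendelian errors
#'
#' A Mendelian error is an opposite-homozygote pair (codes 0 and 2) at a
#' SNP. Errors are detected on the input genotypes over all genotyped
#' sire-offspring pairs; at each conflicting SNP the genotypes of both
#' animals of the pair are then set to missing.
#'
#' @param gm genotype matrix.
#' @param ped a [pedigree()].
#' @return list(genotypes, errors = per-pair error counts, n_errors).
#' @export
mendelian_check <- function(gm, ped) {
  ids <- rownames(gm)
  pairs <- ped[ped$sire != "0" & ped$sire %in% ids & ped$animal %in% ids,
               c("sire", "animal")]
  names(pairs) <- c("sire", "offspring")
  rownames(pairs) <- NULL
  out <- gm
  counts <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    gs <- gm[pairs$sire[k], ]
    go <- gm[pairs$offspring[k], ]
    conflict <- !is.na(gs) & !is.na(go) &
      ((gs == 0L & go == 2L) | (gs == 2L & go == 0L))
    counts[k] <- sum(conflict)
    if (counts[k] > 0L) {
      out[pairs$sire[k], conflict] <- NA_integer_
      out[pairs$offspring[k], conflict] <- NA_integer_
    }
  }
  pairs$n_errors <- counts
  list(genotypes = out, errors = pairs, n_errors = sum(counts))
}

first_degree_pairs <- function(ped, ids) {
  po <- rbind(
    data.frame(a = ped$sire, b = ped$animal, stringsAsFactors = FALSE),
    data.frame(a = ped$dam, b = ped$animal, stringsAsFactors = FALSE)
  )
  po <- po[po$a != "0", ]
  po$type <- "parent_offspring"
  fam <- ped[ped$sire != "0" & ped$dam != "0", ]
  sibs <- NULL
  if (nrow(fam) > 1L) {
    grp <- split(fam$animal, paste(fam$sire, fam$dam))
    grp <- grp[lengths(grp) > 1L]
    if (length(grp)) {
      sibs <- do.call(rbind, lapply(grp, function(g) {
        cmb <- utils::combn(g, 2)
        data.frame(a = cmb[1, ], b = cmb[2, ], type = "full_sibs",
                   stringsAsFactors = FALSE)
      }))
    }
  }
  out <- rbind(po, sibs)
  out[out$a %in% ids & out$b %in% ids, , drop = FALSE]
}

#' Screen for pedigree-versus-genomic relationship discrepancies
#'
#' Flags animals whose pedigree (A) and realized genomic (G) relationship
#' disagree among declared first-degree relatives: either
#' `max |A_ij - G_ij|` over those pairs exceeds the threshold, or a
#' declared parent-offspring pair has `G_ij < 0.5 - threshold`. Catches
#' sample swaps and wrong parentage records.
#'
#' @param A pedigree-based numerator relationship matrix.
#' @param G genomic relationship matrix on the same (or subset of) ids.
#' @param ped a [pedigree()].
#' @param cfg a [qc_config()].
#' @return Character vector of flagged animal ids.
#' @export
relationship_discrepancy_screen <- function(A, G, ped, cfg = qc_config()) {
  ids <- intersect(rownames(A), rownames(G))
  pairs <- first_degree_pairs(ped, ids)
  if (!nrow(pairs)) return(character(0))
  a_val <- A[cbind(pairs$a, pairs$b)]
  g_val <- G[cbind(pairs$a, pairs$b)]
  dev <- abs(a_val - g_val) > cfg$discrepancy_threshold
  po_low <- pairs$type == "parent_offspring" &
    g_val < 0.5 - cfg$discrepancy_threshold
  bad <- dev | po_low
  sort(unique(c(pairs$a[bad], pairs$b[bad])))
}

#' Run the full QC cascade
#'
#' Applies, in order: excluded chromosomes, duplicate positions, animal
#' call rate, SNP call rate, MAF, Hardy-Weinberg, Mendelian consistency
#' and (optionally) the pedigree-versus-genomic relationship screen, with
#' per-step exclusion accounting. Frequencies and missingness are
#' recomputed after each step.
#'
#' @param gm genotype matrix.
#' @param map aligned [marker_map()].
#' @param ped a [pedigree()] (needed for the Mendelian and relationship
#'   steps; pass `NULL` to skip them).
#' @param cfg a [qc_config()].
#' @param screen_relationships run the A-versus-G discrepancy screen
#'   (computes a genomic relationship matrix internally).
#' @return A list of class `qc_result` with `genotypes`, `map`, `report`
#'   (per-step counts), `mendelian` (per-pair error table) and
#'   `flagged_animals`.
#' @export
run_qc <- function(gm, map, ped = NULL, cfg = qc_config(),
                   screen_relationships = !is.null(ped)) {
  stop_if_not_genotypes(gm)
  gm <- align_genotypes(gm, map)
  steps <- list()
  note <- function(step, snps, animals) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, snps_removed = length(snps),
      animals_removed = length(animals), stringsAsFactors = FALSE)
  }

  r <- filter_chromosomes(gm, map, cfg)
  note("excluded_chromosomes", r$removed_snps, character(0))
  r2 <- drop_duplicate_positions(r$genotypes, r$map)
  note("duplicate_positions", r2$removed_snps, character(0))
  r3 <- filter_missingness(r2$genotypes, r2$map, cfg)
  note("animal_call_rate", character(0), r3$removed_animals)
  note("snp_call_rate", r3$removed_snps, character(0))
  r4 <- filter_maf_hwe(r3$genotypes, r3$map, cfg)
  note("maf", r4$removed_maf, character(0))
  note("hwe", r4$removed_hwe, character(0))

  gm <- r4$genotypes
  map <- r4$map
  mendel <- NULL
  flagged <- character(0)
  if (!is.null(ped)) {
    mc <- mendelian_check(gm, ped)
    gm <- mc$genotypes
    mendel <- mc$errors
    note("mendelian", character(0), character(0))
    if (screen_relationships && nrow(gm) > 1L) {
      A <- build_nrm(ped)
      common <- intersect(rownames(gm), rownames(A))
      G <- build_grm(gm[common, , drop = FALSE])
      flagged <- relationship_discrepancy_screen(
        A[common, common], G, ped, cfg)
      gm <- gm[setdiff(rownames(gm), flagged), , drop = FALSE]
      note("relationship_discrepancy", character(0), flagged)
    }
  }
  report <- do.call(rbind, steps)
  structure(list(genotypes = gm, map = map, report = report,
                 mendelian = mendel, flagged_animals = flagged),
            class = "qc_result")
}
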