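masked_cells <- function(truth, imputed, scenario) {
  tv <- truth[scenario$validation, scenario$masked, drop = FALSE]
  iv <- imputed[scenario$validation, scenario$masked, drop = FALSE]
  list(truth = tv, imputed = iv)
}

#' Genotypic and allelic concordance over masked cells
#'
#' `correct_genotypes` is the fraction of masked cells whose discrete code
#' is reproduced exactly; `correct_alleles` gives partial credit
#' `(2 - |g_true - g_imp|) / 2` per cell, i.e. the fraction of correctly
#' imputed alleles without regard to phase. A correct genotype implies two
#' correct alleles, so `correct_genotypes <= correct_alleles` always.
#'
#' @param truth true genotype matrix.
#' @param imputed imputed genotype matrix (discrete codes).
#' @param scenario the `imputation_scenario` defining masked cells.
#' @return list(correct_alleles, correct_genotypes, n_cells).
#' @export
concordance <- function(truth, imputed, scenario) {
  mc <- masked_cells(truth, imputed, scenario)
  d <- abs(mc$truth - mc$imputed)
  list(correct_alleles = mean((2 - d) / 2),
       correct_genotypes = mean(d == 0),
       n_cells = length(d))
}

#' Correlation between true and imputed genotypes
#'
#' Pearson correlation of true versus imputed genotype codes (dosages when
#' supplied) over the masked cells of a group. Per-animal values use each
#' validation animal's masked cells; the per-chromosome summary reports
#' both the mean of per-animal correlations (the headline figure) and the
#' correlation pooled over all masked cells of the chromosome. Groups
#' without variance in either vector are returned as `NA` and counted.
#'
#' @param truth true genotype matrix.
#' @param imputed imputed genotype matrix.
#' @param scenario the `imputation_scenario`.
#' @param by `"animal"` or `"chromosome"`.
#' @param map marker map (required for `by = "chromosome"`).
#' @param dosage optional dosage matrix to correlate instead of the
#'   discrete codes.
#' @return For `by = "animal"`: data.frame(animal, r, n_cells). For
#'   `by = "chromosome"`: data.frame(chrom, r_mean_animal, r_pooled,
#'   n_animals_excluded).
#' @export
r_tg_ig <- function(truth, imputed, scenario, by = c("animal", "chromosome"),
                    map = NULL, dosage = NULL) {
  by <- match.arg(by)
  imp <- dosage %||% imputed
  per_animal <- function(snps) {
    vapply(scenario$validation, function(a) {
      x <- truth[a, snps]
      y <- imp[a, snps]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(x[ok], y[ok])
    }, numeric(1))
  }
  if (by == "animal") {
    r <- per_animal(scenario$masked)
    return(data.frame(animal = scenario$validation, r = unname(r),
                      n_cells = length(scenario$masked),
                      stringsAsFactors = FALSE))
  }
  if (is.null(map)) stop("per-chromosome grouping needs the marker map")
  chroms <- unique(map$chrom)
  out <- lapply(chroms, function(ch) {
    snps <- intersect(map$snp_id[map$chrom == ch], scenario$masked)
    if (!length(snps)) return(NULL)
    r_an <- per_animal(snps)
    x <- as.vector(truth[scenario$validation, snps])
    y <- as.vector(imp[scenario$validation, snps])
    ok <- !is.na(x) & !is.na(y)
    pooled <- if (sum(ok) > 1L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0)
      stats::cor(x[ok], y[ok]) else NA_real_
    data.frame(chrom = ch, r_mean_animal = mean(r_an, na.rm = TRUE),
               r_pooled = pooled, n_animals_excluded = sum(is.na(r_an)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Allelic concordance as a function of allele frequency (LOESS)
#'
#' For every masked SNP and each of its two alleles, computes the fraction
#' of that allele's true occurrences that were imputed correctly (counting
#' per-cell matched copies, `min(g_true, g_imp)` for allele b), paired with
#' the allele's reference-population frequency; both alleles contribute a
#' point, so the frequency axis spans the full unit interval. A
#' locally-weighted degree-1 regression (tricube weights) with the given
#' span is evaluated on an equispaced frequency grid, predictions clamped
#' to the observed concordance range intersected with [0, 1].
#'
#' @param truth,imputed genotype matrices.
#' @param scenario the `imputation_scenario`.
#' @param freqs named allele_b reference frequencies per SNP.
#' @param span LOESS smoothing parameter (default 0.1).
#' @param grid_n number of evaluation points on [0, 1] (default 101).
#' @return list(`points` = per-allele raw points, `curve` =
#'   data.frame(frequency, concordance)).
#' @export
frequency_stratified_accuracy <- function(truth, imputed, scenario, freqs,
                                          span = 0.1, grid_n = 101L) {
  mc <- masked_cells(truth, imputed, scenario)
  tv <- mc$truth
  iv <- mc$imputed
  nb_true <- colSums(tv)
  nb_hit <- colSums(pmin(tv, iv))
  na_true <- colSums(2L - tv)
  na_hit <- colSums(pmin(2L - tv, 2L - iv))
  p <- freqs[colnames(tv)]
  pts <- rbind(
    data.frame(snp_id = colnames(tv), allele = "b", frequency = unname(p),
               concordance = unname(nb_hit / nb_true),
               n_alleles = unname(nb_true), stringsAsFactors = FALSE),
    data.frame(snp_id = colnames(tv), allele = "a",
               frequency = unname(1 - p),
               concordance = unname(na_hit / na_true),
               n_alleles = unname(na_true), stringsAsFactors = FALSE)
  )
  pts <- pts[pts$n_alleles > 0 & !is.na(pts$frequency), , drop = FALSE]
  rownames(pts) <- NULL
  if (nrow(pts) < 10L) stop("need at least 10 (frequency, concordance) points")
  ## small spans routinely trigger near-singular local fits that loess
  ## resolves by pseudoinverse; those warnings are expected, not actionable
  fit <- suppressWarnings(
    stats::loess(concordance ~ frequency, data = pts, span = span,
                 degree = 1, family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  grid <- seq(0, 1, length.out = grid_n)
  pred <- suppressWarnings(
    stats::predict(fit, newdata = data.frame(frequency = grid)))
  lo <- max(0, min(pts$concordance))
  hi <- min(1, max(pts$concordance))
  curve <- data.frame(frequency = grid,
                      concordance = pmin(pmax(pred, lo), hi))
  list(points = pts, curve = curve)
}

#' Imputation accuracy by number of close relatives in the reference
#'
#' Joins per-animal correlations to the validation animals' reference
#' relative counts and summarizes mean accuracy for animals with 0, 1 and
#' 2 or more close relatives (relationship above the profile threshold).
#'
#' @param per_animal_r data.frame from [r_tg_ig()] (`by = "animal"`).
#' @param profile data.frame from [relatives_profile()].
#' @return list(`per_animal` = joined table with a `close_bin` factor,
#'   `summary` = mean r and counts per bin).
#' @export
accuracy_vs_relatives <- function(per_animal_r, profile) {
  merged <- merge(per_animal_r, profile, by = "animal", sort = FALSE)
  if (nrow(merged) != nrow(per_animal_r)) {
    stop("relatives profile does not cover all validation animals")
  }
  merged$close_bin <- cut(merged$n_close, breaks = c(-Inf, 0, 1, Inf),
                          labels = c("0", "1", "2+"))
  agg <- stats::aggregate(r ~ close_bin, data = merged, FUN = mean,
                          na.rm = TRUE, drop = FALSE)
  agg$n_animals <- as.vector(table(merged$close_bin))
  names(agg) <- c("close_relatives", "mean_r", "n_animals")
  list(per_animal = merged, summary = agg)
}
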