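#' Build a masking scenario
#'
#' Splits animals into reference and validation populations and masks, for
#' validation animals only, every SNP that is not on the low-density panel
#' (the `in_panel` flag of the map). Reference rows are left untouched.
#'
#' @param gm genotype matrix (animals x SNP).
#' @param map aligned [marker_map()] with panel flags.
#' @param reference,validation disjoint animal id sets.
#' @return list(`scenario` = object of class `imputation_scenario` with the
#'   id partition, `genotypes` = masked matrix).
#' @export
make_scenario <- function(gm, map, reference, validation) {
  stop_if_not_genotypes(gm)
  if (any(reference %in% validation)) {
    stop("reference and validation sets must be disjoint")
  }
  stopifnot(all(c(reference, validation) %in% rownames(gm)))
  if (!any(map$in_panel)) stop("map carries no panel flags")
  gm <- align_genotypes(gm, map)
  masked <- map$snp_id[!map$in_panel]
  retained <- map$snp_id[map$in_panel]
  out <- gm
  out[validation, masked] <- NA_integer_
  scenario <- structure(list(reference = reference, validation = validation,
                             masked = masked, retained = retained),
                        class = "imputation_scenario")
  list(scenario = scenario, genotypes = out)
}

#' @export
print.imputation_scenario <- function(x, ...) {
  cat(sprintf(
    "imputation scenario: %d reference, %d validation animals; %d of %d SNP masked (%.2f%%)\n",
    length(x$reference), length(x$validation), length(x$masked),
    length(x$masked) + length(x$retained),
    100 * length(x$masked) / (length(x$masked) + length(x$retained))))
  invisible(x)
}

#' Fill missing genotypes from reference allele frequencies
#'
#' Deterministic modal fill: a missing genotype becomes the homozygote of
#' the more frequent allele (2 if the allele_b frequency exceeds 0.5, 0 if
#' below) and the heterozygote 1 at an exact 0.5 tie. The expected allelic
#' concordance of this filler at allele frequency p is `max(p, 1 - p)`.
#'
#' @param gm genotype matrix with missing entries.
#' @param freqs named allele_b frequencies (typically from the reference
#'   population, see [allele_frequency()]).
#' @return The matrix with all missing entries of SNP named in `freqs`
#'   filled.
#' @export
frequency_fill <- function(gm, freqs) {
  snps <- intersect(colnames(gm), names(freqs))
  fill <- ifelse(freqs[snps] > 0.5, 2L, ifelse(freqs[snps] < 0.5, 0L, 1L))
  for (j in snps) {
    miss <- is.na(gm[, j])
    if (any(miss)) gm[miss, j] <- fill[[j]]
  }
  gm
}

imputation_result <- function(genotypes, dosage, residual_missing, imputer,
                              params = list()) {
  structure(list(genotypes = genotypes, dosage = dosage,
                 residual_missing = residual_missing, imputer = imputer,
                 params = params),
            class = "imputation_result")
}

#' Impute masked genotypes with the built-in haplotype-copying HMM
#'
#' A Li-Stephens-style hidden Markov model imputes each validation
#' haplotype against a panel of reference haplotypes, conditioning on the
#' typed (panel) sites. State switches occur with probability
#' `1 - exp(-rho * d)` over a gap of `d` bp; emissions match the observed
#' allele with probability `1 - eps`. The dosage of an untyped site is the
#' posterior-weighted reference allele, summed over the animal's two
#' haplotypes; discrete codes round the dosage with half-way ties going to
#' the heterozygote.
#'
#' The two haplotypes of a diploid animal are imputed as two independent
#' haploid chains, which equals the joint diploid chain when the phase at
#' typed sites is known (here supplied by `val_haps`, e.g. simulator truth
#' phase at panel sites).
#'
#' @param scenario an `imputation_scenario` from [make_scenario()].
#' @param genotypes the masked genotype matrix of the scenario (used for
#'   typed-site output and reference allele frequencies).
#' @param map aligned, sorted [marker_map()].
#' @param ref_haps reference haplotypes: matrix of 0/1 alleles, one row per
#'   haplotype (see [truth_haplotypes()]), columns covering all SNP.
#' @param val_haps validation haplotypes, two rows per validation animal
#'   named `<id>.1` / `<id>.2`; only panel-site columns are read.
#' @param rho per-bp switch intensity (default 1e-6).
#' @param eps allele error probability (default 0.002).
#' @param n_states optional cap K on the number of reference haplotypes
#'   used (first K rows); K < 2 is an error.
#' @return An `imputation_result` with discrete genotypes, dosages, the
#'   per-SNP count of residual missing genotypes before any fill, and the
#'   imputer parameters.
#' @export
hmm_impute <- function(scenario, genotypes, map, ref_haps, val_haps,
                       rho = 1e-6, eps = 0.002, n_states = NULL) {
  if (!map_is_sorted(map)) stop("marker map must be sorted")
  K <- n_states %||% nrow(ref_haps)
  if (K < 2L) stop("at least two reference haplotype states required")
  K <- min(K, nrow(ref_haps))
  ref_haps <- ref_haps[seq_len(K), , drop = FALSE]

  val <- scenario$validation
  h_names <- as.vector(rbind(paste0(val, ".1"), paste0(val, ".2")))
  stopifnot(all(h_names %in% rownames(val_haps)))

  n_snp <- nrow(map)
  dosage <- matrix(NA_real_, length(val), n_snp,
                   dimnames = list(val, map$snp_id))
  typed_set <- map$snp_id %in% scenario$retained

  for (ch in unique(map$chrom)) {
    on_ch <- map$chrom == ch
    snps <- map$snp_id[on_ch]
    pos <- map$pos[on_ch]
    typed <- typed_set[on_ch]
    R_all <- ref_haps[, snps, drop = FALSE]
    O <- val_haps[h_names, snps[typed], drop = FALSE]
    ## mask typed observations that are missing in the scenario genotypes
    obs_g <- genotypes[val, snps[typed], drop = FALSE]
    miss_g <- is.na(obs_g)
    if (any(miss_g)) {
      idx <- which(miss_g, arr.ind = TRUE)
      O[cbind(2L * idx[, 1] - 1L, idx[, 2])] <- NA_integer_
      O[cbind(2L * idx[, 1], idx[, 2])] <- NA_integer_
    }
    dh <- ls_haploid_dosage(O, R_all, typed, pos, rho, eps)
    odd <- seq(1L, nrow(dh), by = 2L)
    dosage[, snps] <- dh[odd, , drop = FALSE] + dh[odd + 1L, , drop = FALSE]
  }
  ## typed sites with an observed genotype pass through unchanged
  obs <- genotypes[val, , drop = FALSE]
  keep <- !is.na(obs) & matrix(typed_set, length(val), n_snp, byrow = TRUE)
  dosage[keep] <- obs[keep]

  dosage <- pmin(pmax(dosage, 0), 2)   # shave floating-point spillover
  disc <- round_genotype(dosage)
  residual <- colSums(is.na(disc[, scenario$masked, drop = FALSE]))
  imputation_result(disc, dosage, residual, "hmm_ls",
                    list(n_states = K, rho = rho, eps = eps))
}

#' Run an external imputation tool through a file-based adapter
#'
#' Writes the masked genotypes as VCF, substitutes `{input}` and
#' `{output}` into the tool's command template, runs it, parses the output
#' VCF back, counts residual missing genotypes among the masked cells and
#' fills them from reference allele frequencies.
#'
#' @param scenario an `imputation_scenario`.
#' @param genotypes masked genotype matrix.
#' @param map aligned [marker_map()].
#' @param tool list with `name` and `command` (a template containing
#'   `{input}` and `{output}` placeholders).
#' @param workdir directory for the exchange files (default a tempdir).
#' @return An `imputation_result` for the validation animals over all SNP.
#' @export
external_imputer_adapter <- function(scenario, genotypes, map, tool,
                                     workdir = tempfile("imputer")) {
  stopifnot(is.list(tool), !is.null(tool$command), !is.null(tool$name))
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  input <- file.path(workdir, "input.vcf")
  output <- file.path(workdir, "output.vcf")
  write_vcf(genotypes, map, input)
  cmd <- gsub("{input}", input, tool$command, fixed = TRUE)
  cmd <- gsub("{output}", output, cmd, fixed = TRUE)
  exe <- strsplit(trimws(cmd), "[[:space:]]+")[[1]][1]
  if (Sys.which(exe) == "" && !file.exists(exe)) {
    stop("imputation tool not found: ", exe)
  }
  status <- system(cmd)
  if (status != 0L || !file.exists(output)) {
    stop("imputation tool '", tool$name, "' failed (exit status ", status, ")")
  }
  parsed <- tryCatch(read_vcf(output), error = function(e) {
    stop("malformed output from tool '", tool$name, "': ",
         conditionMessage(e))
  })
  out <- parsed$genotypes
  missing_animals <- setdiff(scenario$validation, rownames(out))
  missing_snps <- setdiff(map$snp_id, colnames(out))
  if (length(missing_animals) || length(missing_snps)) {
    stop("tool output lacks ", length(missing_animals), " animals and ",
         length(missing_snps), " SNP")
  }
  out <- out[scenario$validation, map$snp_id, drop = FALSE]
  residual <- colSums(is.na(out[, scenario$masked, drop = FALSE]))
  freqs <- allele_frequency(genotypes[scenario$reference, , drop = FALSE])
  filled <- frequency_fill(out, freqs)
  imputation_result(filled, NULL, residual, tool$name,
                    list(command = tool$command))
}
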