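#' Per-SNP imputation error proportions
#'
#' Fraction of validation animals with a discrete-code mismatch at each
#' masked SNP — the statistic driving the misplaced-SNP detector.
#'
#' @param truth,imputed genotype matrices.
#' @param scenario the `imputation_scenario`.
#' @return Named numeric vector over the masked SNP.
#' @export
snp_error_proportion <- function(truth, imputed, scenario) {
  mc <- masked_cells(truth, imputed, scenario)
  colMeans(mc$truth != mc$imputed, na.rm = TRUE)
}

#' Detect misplaced SNP from locally elevated imputation error
#'
#' Chromosomes are tiled into half-open segments of `segment_bp`
#' (anchored at position 1, so a SNP at position p falls in segment
#' `floor((p - 1) / segment_bp)`). A SNP is "high-error" when its error
#' proportion strictly exceeds `err_thresh`. If a segment contains
#' strictly more than `count_thresh` high-error SNP, every SNP of the
#' segment is flagged (`segment_flag`) — the signature of a misplaced
#' stretch of map; otherwise only the high-error SNP themselves are
#' flagged (`individual_flag`).
#'
#' @param error_prop named per-SNP error proportions (masked SNP).
#' @param map sorted [marker_map()].
#' @param segment_bp segment width in bp (default 5e5).
#' @param err_thresh high-error threshold on the error proportion
#'   (default 0.10, strict).
#' @param count_thresh segment rule threshold (default 10: "more than
#'   ten" high-error SNP, strict).
#' @return A list of class `misplaced_report`: `flagged` (snp_id, chrom,
#'   pos, segment bounds, error_prop, reason) and `segments` (per-segment
#'   statistics).
#' @export
detect_misplaced <- function(error_prop, map, segment_bp = 5e5,
                             err_thresh = 0.10, count_thresh = 10L) {
  if (!map_is_sorted(map)) stop("marker map must be sorted")
  err <- error_prop[match(map$snp_id, names(error_prop))]
  seg <- (map$pos - 1L) %/% segment_bp
  key <- paste(map$chrom, seg, sep = ":")
  high <- !is.na(err) & err > err_thresh

  n_high <- tapply(high, key, sum)
  n_snp <- tapply(high, key, length)
  seg_flagged <- names(n_high)[n_high > count_thresh]

  in_flagged_seg <- key %in% seg_flagged
  take <- in_flagged_seg | high
  reason <- ifelse(in_flagged_seg, "segment_flag", "individual_flag")

  flagged <- data.frame(
    snp_id = map$snp_id[take],
    chrom = map$chrom[take],
    pos = map$pos[take],
    segment_start = seg[take] * segment_bp + 1L,
    segment_end = (seg[take] + 1L) * segment_bp,
    error_prop = unname(err[take]),
    reason = reason[take],
    stringsAsFactors = FALSE
  )
  rownames(flagged) <- NULL
  uk <- !duplicated(key)
  segments <- data.frame(
    chrom = map$chrom[uk],
    start = seg[uk] * segment_bp + 1L,
    end = (seg[uk] + 1L) * segment_bp,
    n_snp = as.vector(n_snp[key[uk]]),
    n_high_error = as.vector(n_high[key[uk]]),
    flagged = key[uk] %in% seg_flagged,
    stringsAsFactors = FALSE
  )
  rownames(segments) <- NULL
  structure(list(flagged = flagged, segments = segments,
                 segment_bp = segment_bp, err_thresh = err_thresh,
                 count_thresh = count_thresh),
            class = "misplaced_report")
}

#' Localize a (possibly misplaced) SNP by linkage disequilibrium
#'
#' Computes the composite genotypic r-squared between the query SNP and
#' every other SNP (so the check runs on unphased data), tiles the genome
#' into windows of `window_bp` and returns the window whose SNP carry the
#' highest median r-squared with the query — the likely true location —
#' provided that median reaches `min_r2`; otherwise the SNP is reported
#' unresolved.
#'
#' @param gm genotype matrix (all genotyped animals, unmasked).
#' @param map aligned [marker_map()].
#' @param snp_id the query SNP (must be polymorphic).
#' @param window_bp window width (default 1 Mb).
#' @param min_r2 minimum supporting median r-squared (default 0.1).
#' @param min_snps minimum SNP per window for a median (default 3).
#' @return list(snp_id, resolved, chrom, start, end, median_r2).
#' @export
ld_localize <- function(gm, map, snp_id, window_bp = 1e6, min_r2 = 0.1,
                        min_snps = 3L) {
  stopifnot(snp_id %in% map$snp_id)
  x <- gm[, snp_id]
  if (stats::sd(x, na.rm = TRUE) == 0) {
    stop("query SNP is monomorphic; no LD signal")
  }
  r2 <- suppressWarnings(
    drop(stats::cor(gm[, map$snp_id, drop = FALSE], x,
                    use = "pairwise.complete.obs"))^2
  )
  names(r2) <- map$snp_id
  r2[snp_id] <- NA                     # exclude self
  win <- paste(map$chrom, (map$pos - 1L) %/% window_bp, sep = ":")
  meds <- tapply(r2, win, stats::median, na.rm = TRUE)
  sizes <- tapply(!is.na(r2), win, sum)
  meds[sizes < min_snps] <- NA
  if (all(is.na(meds))) {
    return(list(snp_id = snp_id, resolved = FALSE, chrom = NA_character_,
                start = NA_integer_, end = NA_integer_,
                median_r2 = NA_real_))
  }
  best <- names(meds)[which.max(meds)]
  best_med <- meds[[best]]
  parts <- strsplit(best, ":", fixed = TRUE)[[1]]
  w <- as.integer(parts[2])
  if (is.na(best_med) || best_med < min_r2) {
    return(list(snp_id = snp_id, resolved = FALSE, chrom = NA_character_,
                start = NA_integer_, end = NA_integer_,
                median_r2 = if (is.na(best_med)) NA_real_ else best_med))
  }
  list(snp_id = snp_id, resolved = TRUE, chrom = parts[1],
       start = w * window_bp + 1, end = (w + 1) * window_bp,
       median_r2 = best_med)
}
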