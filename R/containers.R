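#' Construct a marker map
#'
#' A marker map is an ordered table of SNP records: identifier, chromosome
#' label, 1-based physical position, the two allele labels and a flag
#' marking membership of the low-density panel (the medium-density chip
#' analogue). Genotype codes count copies of `allele_b`; the orientation is
#' fixed when data are read and never flipped silently.
#'
#' @param snp_id unique SNP identifiers.
#' @param chrom chromosome labels.
#' @param pos 1-based physical positions in bp.
#' @param allele_a,allele_b allele labels (A-coded allele is the one whose
#'   copy number is NOT counted).
#' @param in_panel logical, SNP belongs to the low-density panel.
#' @return A `data.frame` of class `marker_map`, sorted by
#'   (chromosome, position).
#' @export
marker_map <- function(snp_id, chrom, pos, allele_a = "A", allele_b = "B",
                       in_panel = FALSE) {
  map <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    allele_a = rep_len(as.character(allele_a), length(snp_id)),
    allele_b = rep_len(as.character(allele_b), length(snp_id)),
    in_panel = rep_len(as.logical(in_panel), length(snp_id)),
    stringsAsFactors = FALSE
  )
  map <- sort_map(map)
  validate_map(map)
  map
}

sort_map <- function(map) {
  r <- chrom_rank(map$chrom)
  map <- map[order(r$rank, r$label, map$pos, map$snp_id), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- unique(c("marker_map", class(map)))
  map
}

validate_map <- function(map, allow_duplicates = TRUE) {
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b", "in_panel")
  if (!all(need %in% names(map))) {
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(map$snp_id)) stop("SNP identifiers must be unique")
  if (any(map$pos < 1L, na.rm = TRUE)) stop("positions are 1-based (>= 1)")
  if (!allow_duplicates &&
      anyDuplicated(paste(map$chrom, map$pos))) {
    stop("duplicate (chromosome, position) pairs present")
  }
  invisible(map)
}

map_is_sorted <- function(map) {
  r <- chrom_rank(map$chrom)
  o <- order(r$rank, r$label, map$pos)
  identical(o, seq_len(nrow(map)))
}

#' Align genotype matrix columns to a marker map
#'
#' @param gm genotype matrix (animals x SNP).
#' @param map marker map whose `snp_id` order defines the column order.
#' @return `gm` with columns reordered/subset to `map$snp_id`.
#' @export
align_genotypes <- function(gm, map) {
  missing <- setdiff(map$snp_id, colnames(gm))
  if (length(missing)) {
    stop("genotype matrix lacks ", length(missing), " SNP of the map, e.g. ",
         missing[1])
  }
  gm[, map$snp_id, drop = FALSE]
}

#' Construct a pedigree table
#'
#' @param animal animal identifiers (unique).
#' @param sire,dam parent identifiers; `"0"` (or `NA`) marks an unknown
#'   parent.
#' @param birth_year integer birth years (optional, `NA` allowed).
#' @return A `data.frame` of class `pedigree`.
#' @export
pedigree <- function(animal, sire = "0", dam = "0", birth_year = NA_integer_) {
  ped <- data.frame(
    animal = as.character(animal),
    sire = as.character(sire),
    dam = as.character(dam),
    birth_year = as.integer(birth_year),
    stringsAsFactors = FALSE
  )
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  if (anyDuplicated(ped$animal)) stop("animal identifiers must be unique")
  class(ped) <- unique(c("pedigree", class(ped)))
  ped
}

#' Topologically order a pedigree (parents before offspring)
#'
#' Errors if the pedigree contains a cycle (an animal that is its own
#' ancestor) or names a parent without a record.
#'
#' @param ped a [pedigree()] table.
#' @return The pedigree reordered so every parent precedes its offspring.
#' @export
order_pedigree <- function(ped) {
  ids <- ped$animal
  known_parents <- setdiff(unique(c(ped$sire, ped$dam)), "0")
  absent <- setdiff(known_parents, ids)
  if (length(absent)) {
    stop("parents without a pedigree record: ", paste(absent, collapse = ", "))
  }
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  n <- length(ids)
  placed <- logical(n)
  out <- integer(0)
  remaining <- seq_len(n)
  repeat {
    ready <- remaining[
      (is.na(si[remaining]) | placed[si[remaining]]) &
      (is.na(di[remaining]) | placed[di[remaining]])
    ]
    if (!length(ready)) {
      if (!length(remaining)) break
      stop("pedigree contains a cycle")
    }
    placed[ready] <- TRUE
    out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
    if (!length(remaining)) break
  }
  ped[out, , drop = FALSE]
}

is_founder <- function(ped) ped$sire == "0" & ped$dam == "0"
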