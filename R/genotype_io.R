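#' Read genotypes and a marker map
#'
#' Genotype codes count copies of `allele_b` (the VCF ALT allele), so GT
#' `0/1` maps to code 1 and `./.` to missing. The coding orientation is
#' fixed here and never flipped downstream.
#'
#' @param path file path; for `format = "pedmap"` the common prefix of the
#'   `.ped`/`.map` pair.
#' @param format `"vcf"` or `"pedmap"`.
#' @param map optional reference [marker_map()] supplying allele labels for
#'   the ped/map dialect; alleles that do not match it are an error.
#' @return A list with `genotypes` (animals x SNP integer matrix) and
#'   `map` (a [marker_map()]).
#' @export
read_genotypes <- function(path, format = c("vcf", "pedmap"), map = NULL) {
  format <- match.arg(format)
  switch(format,
    vcf = read_vcf(path),
    pedmap = read_pedmap(path, map = map)
  )
}

#' Write genotypes and a marker map
#'
#' @param gm genotype matrix (animals x SNP, codes 0/1/2/NA).
#' @param map the aligned [marker_map()].
#' @param path output path (prefix for `"pedmap"`).
#' @param format `"vcf"` or `"pedmap"`.
#' @return Invisibly, the path written.
#' @export
write_genotypes <- function(gm, map, path, format = c("vcf", "pedmap")) {
  format <- match.arg(format)
  switch(format,
    vcf = write_vcf(gm, map, path),
    pedmap = write_pedmap(gm, map, path)
  )
}

read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  map <- marker_map(
    snp_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    allele_a = fix$REF, allele_b = fix$ALT, in_panel = FALSE
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  gm <- matrix(codes[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  gm <- t(gm)                                   # animals x SNP
  gm <- gm[, map$snp_id, drop = FALSE]
  storage.mode(gm) <- "integer"
  list(genotypes = gm, map = map)
}

write_vcf <- function(gm, map, path) {
  stop_if_not_genotypes(gm)
  gm <- align_genotypes(gm, map)
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow(gm), ncol(gm))
  ok <- !is.na(gm)
  body[ok] <- gt_codes[gm[ok] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=keyimpute",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm)), collapse = "\t")
  )
  fix <- paste(map$chrom, map$pos, map$snp_id, map$allele_a, map$allele_b,
               ".", "PASS", ".", "GT", sep = "\t")
  lines <- paste(fix, apply(body, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

write_pedmap <- function(gm, map, prefix) {
  stop_if_not_genotypes(gm)
  gm <- align_genotypes(gm, map)
  utils::write.table(
    data.frame(map$chrom, map$snp_id, 0, map$pos),
    paste0(prefix, ".map"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  n_snp <- ncol(gm)
  lines <- vapply(seq_len(nrow(gm)), function(i) {
    g <- gm[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, map$allele_b, map$allele_a))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, map$allele_b, map$allele_a))
    paste(c(rownames(gm)[i], rownames(gm)[i], "0", "0", "0", "-9",
            as.vector(rbind(a1, a2))), collapse = "\t")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

read_pedmap <- function(prefix, map = NULL) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path)) {
    if (!file.exists(p)) stop("no such file: ", p)
  }
  raw_map <- utils::read.table(map_path, sep = "\t",
                               col.names = c("chrom", "snp_id", "cm", "pos"),
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  if (is.null(map)) {
    ## without a reference map, allele labels are oriented lexicographically
    mm <- marker_map(raw_map$snp_id, raw_map$chrom, raw_map$pos)
  } else {
    missing <- setdiff(raw_map$snp_id, map$snp_id)
    if (length(missing)) {
      stop("SNP absent from the reference map, e.g. ", missing[1])
    }
    mm <- map[match(raw_map$snp_id, map$snp_id), , drop = FALSE]
    mm <- sort_map(mm)
  }
  lines <- readLines(ped_path)
  n_snp <- nrow(raw_map)
  want <- 6L + 2L * n_snp
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(toks)
  if (any(nfield != want)) {
    i <- which(nfield != want)[1]
    stop(sprintf("malformed .ped line %d: %d fields, expected %d",
                 i, nfield[i], want))
  }
  tok <- do.call(rbind, toks)
  animals <- tok[, 2]
  A1 <- tok[, seq(7L, by = 2L, length.out = n_snp), drop = FALSE]
  A2 <- tok[, seq(8L, by = 2L, length.out = n_snp), drop = FALSE]
  if (is.null(map)) {
    ## no reference map: orient each SNP by sorting its observed labels,
    ## the lexicographically smaller becoming allele_a
    ref <- mm$allele_a
    alt <- mm$allele_b
    for (j in seq_len(n_snp)) {
      seen <- sort(unique(c(A1[, j], A2[, j])))
      seen <- setdiff(seen, "0")
      if (length(seen) > 2L) {
        stop("more than two alleles observed for SNP ", raw_map$snp_id[j])
      }
      if (length(seen) >= 1L) ref[j] <- seen[1]
      if (length(seen) == 2L) alt[j] <- seen[2]
    }
    mm$allele_a[match(raw_map$snp_id, mm$snp_id)] <- ref
    mm$allele_b[match(raw_map$snp_id, mm$snp_id)] <- alt
  } else {
    ref <- mm$allele_a[match(raw_map$snp_id, mm$snp_id)]
    alt <- mm$allele_b[match(raw_map$snp_id, mm$snp_id)]
    refm <- matrix(ref, nrow(A1), n_snp, byrow = TRUE)
    altm <- matrix(alt, nrow(A1), n_snp, byrow = TRUE)
    bad <- (!(A1 == "0" | A1 == refm | A1 == altm)) |
           (!(A2 == "0" | A2 == refm | A2 == altm))
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("allele mismatch on .ped line %d at SNP %s",
                   w[1], raw_map$snp_id[w[2]]))
    }
  }
  altm <- matrix(alt, nrow(A1), n_snp, byrow = TRUE)
  gm <- (A1 == altm) + (A2 == altm)
  gm[A1 == "0" | A2 == "0"] <- NA_integer_
  storage.mode(gm) <- "integer"
  dimnames(gm) <- list(animals, raw_map$snp_id)
  list(genotypes = gm[, mm$snp_id, drop = FALSE], map = mm)
}

#' Read / write a pedigree CSV
#'
#' Columns `animal,sire,dam,birth_year`; `0` encodes an unknown parent.
#'
#' @param ped a [pedigree()] table (for writing).
#' @param path file path.
#' @return `read_pedigree_csv()` returns a [pedigree()];
#'   `write_pedigree_csv()` returns the path invisibly.
#' @export
write_pedigree_csv <- function(ped, path) {
  utils::write.csv(as.data.frame(ped)[, c("animal", "sire", "dam",
                                          "birth_year")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(animal = "character",
                                            sire = "character",
                                            dam = "character"))
  pedigree(d$animal, d$sire, d$dam, d$birth_year)
}

#' Write a marker map as TSV (with panel flags)
#'
#' @param map a [marker_map()].
#' @param path file path.
#' @return The path, invisibly (reader: the map).
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(snp_id = "character",
                                        chrom = "character"))
  marker_map(d$snp_id, d$chrom, d$pos, d$allele_a, d$allele_b, d$in_panel)
}

#' Write a report table or nested summary
#'
#' Data frames become schema-stable TSV (an empty report yields a
#' header-only file); lists become JSON.
#'
#' @param report a `data.frame` or list.
#' @param path file path (`.tsv` or `.json` by content).
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  if (is.data.frame(report)) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (is.list(report)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else {
    stop("report must be a data.frame or a list")
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path file path.
#' @return The parsed list with vectors simplified.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a genotype matrix as plain TSV
#'
#' Used for truth sidecars inside pipeline run directories.
#'
#' @param gm integer matrix (animals x SNP).
#' @param path file path.
#' @return The path (writer) / the matrix (reader).
#' @export
write_genotype_tsv <- function(gm, path) {
  d <- data.frame(animal = rownames(gm), gm, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         colClasses = c(animal = "character"))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$animal
  storage.mode(m) <- "integer"
  m
}
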