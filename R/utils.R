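`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed for a named random stream
#'
#' Every stochastic operation in the package draws its seed from a single
#' master seed plus the name of the stage, so that stages are individually
#' reproducible and independent streams do not collide.
#'
#' @param seed integer master seed.
#' @param stream character stream label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  v <- utf8ToInt(stream)
  h <- sum(v * seq_along(v))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 131) %% 2147483647)
}

#' Round dosages to discrete genotype codes
#'
#' Nearest-integer rounding of dosages in `[0, 2]`, with exact half-way
#' values (0.5 and 1.5) resolved to the heterozygote code 1.
#'
#' @param d numeric vector or matrix of dosages in `[0, 2]`.
#' @return Integer codes in `{0, 1, 2}` with the shape of `d`.
#' @export
round_genotype <- function(d) {
  if (any(d < -1e-6 | d > 2 + 1e-6, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  g <- floor(d + 0.5)
  half <- !is.na(d) & (abs(d - 0.5) < 1e-9 | abs(d - 1.5) < 1e-9)
  g[half] <- 1
  g[!is.na(g)] <- pmin(pmax(g[!is.na(g)], 0), 2)
  storage.mode(g) <- "integer"
  g
}

## numeric chromosome-aware ordering: "2" before "10", non-numeric labels last
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(is.na(num), Inf, num)
  list(rank = rank, label = as.character(chrom))
}

stop_if_not_genotypes <- function(gm) {
  if (!is.matrix(gm)) stop("genotypes must be a matrix of codes 0/1/2/NA")
  bad <- !(gm %in% c(0L, 1L, 2L) | is.na(gm))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(rownames(gm)) || is.null(colnames(gm))) {
    stop("genotype matrix must carry animal row names and SNP column names")
  }
  if (anyDuplicated(rownames(gm)) || anyDuplicated(colnames(gm))) {
    stop("animal and SNP identifiers must be unique")
  }
  invisible(gm)
}
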