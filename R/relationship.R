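#' Pedigree-based numerator relationship matrix (tabular method)
#'
#' Recursive tabular construction in topological order:
#' `A[i,i] = 1 + A[s,d]/2` and `A[i,j] = (A[j,s] + A[j,d])/2` for `j`
#' processed before `i`, with unknown parents contributing zero.
#'
#' @param ped a [pedigree()]; a cycle is an error.
#' @return A symmetric matrix with animal ids as dimnames and attribute
#'   `kind = "NRM"`.
#' @export
build_nrm <- function(ped) {
  ped <- order_pedigree(ped)
  ids <- ped$animal
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (!is.na(s)) A[s, j] else 0
      ad_ <- if (!is.na(d)) A[d, j] else 0
      row <- 0.5 * (as_ + ad_)
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  attr(A, "kind") <- "NRM"
  A
}

#' Realized genomic relationship matrix (allele-frequency centered)
#'
#' `G = Z Z' / (2 * sum(p_j (1 - p_j)))` where `Z` is the genotype matrix
#' centered at twice the observed allele_b frequencies. Missing genotypes
#' are mean-imputed per SNP before centering; monomorphic SNP are dropped.
#'
#' @param gm genotype matrix (animals x SNP, codes 0/1/2/NA).
#' @return A symmetric matrix with attribute `kind = "GRM"`.
#' @export
build_grm <- function(gm) {
  m <- gm
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    cm <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m))
    m[idx] <- cm[((idx - 1L) %/% nrow(m)) + 1L]
  }
  p <- colMeans(m) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all SNP are monomorphic; no genomic relationship")
  m <- m[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(m, 2L, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  attr(G, "kind") <- "GRM"
  G
}

## solve A_m x = b through a Cholesky factor, with a ridge fallback for
## singular subsets (e.g. duplicated animals)
chol_subset <- function(Am) {
  tryCatch(chol(Am), error = function(e) {
    warning("relationship subset is numerically singular; ",
            "adding 1e-8 ridge to the diagonal")
    chol(Am + diag(1e-8, nrow(Am)))
  })
}

chol_solve <- function(U, b) {
  backsolve(U, backsolve(U, b, transpose = TRUE))
}

#' Gene-pool contribution of a selected animal subset
#'
#' Solves `A_m p = c_m`, where `A_m` is the relationship matrix restricted
#' to the selected animals and `c` holds each animal's average relationship
#' with the entire population (self included). `p` is the proportion of the
#' population gene pool attributable to each selected animal; its sum is
#' the captured gene-pool fraction, reaching 1 when everyone is selected.
#'
#' @param A numerator relationship matrix over the whole population.
#' @param selected ids of the selected (reference) animals.
#' @return list(`p` = named contribution vector, `sum_p` = captured
#'   fraction).
#' @export
gene_pool_contribution <- function(A, selected) {
  ids <- rownames(A)
  stopifnot(all(selected %in% ids))
  cvec <- rowMeans(A)
  U <- chol_subset(A[selected, selected, drop = FALSE])
  p <- drop(chol_solve(U, cvec[selected]))
  names(p) <- selected
  list(p = p, sum_p = sum(p))
}

#' Write / read a relationship matrix as TSV
#'
#' @param A relationship matrix.
#' @param path file path.
#' @return The path (writer) / the matrix (reader).
#' @export
write_relmat <- function(A, path) {
  d <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         colClasses = c(id = "character"))
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$id
  m
}
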