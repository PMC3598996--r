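#' Greedy selection of key reference animals
#'
#' Animals are added one at a time; each step adds the candidate that
#' maximizes the captured gene-pool fraction `sum(p)` with
#' `p = A_m^-1 c_m` (see [gene_pool_contribution()]). Ties are broken by
#' the lexicographically smaller id, so selection is deterministic, and
#' sets at increasing sizes are nested by construction.
#'
#' The incremental evaluation of every candidate uses a rank-1 extension
#' of the Cholesky factor of the current `A_m`; the result is identical to
#' re-solving the full system at each step.
#'
#' @param A numerator relationship matrix (ids as dimnames).
#' @param sizes ascending vector of snapshot sizes, e.g. `c(50, 100, 200)`.
#' @return A list of class `gene_pool_result`: `selected` (ids in
#'   selection order up to `max(sizes)`), `sum_p` (captured fraction after
#'   each step), `snapshots` (per requested size: ids, `p`, `sum_p`) and
#'   `sizes`.
#' @export
greedy_select <- function(A, sizes) {
  ids <- rownames(A)
  N <- length(ids)
  sizes <- sort(unique(as.integer(sizes)))
  stopifnot(all(sizes >= 1L), max(sizes) <= N)
  m_max <- max(sizes)
  cvec <- rowMeans(A)
  dA <- diag(A)

  sel <- integer(0)
  U <- NULL                # Cholesky factor of A[sel, sel]
  w <- numeric(0)          # current p = A_m^-1 c_m
  v <- numeric(0)          # A_m^-1 1
  sum_trace <- numeric(m_max)
  snapshots <- list()

  for (step in seq_len(m_max)) {
    cand <- setdiff(seq_len(N), sel)
    if (!length(sel)) {
      val <- cvec[cand] / dA[cand]
    } else {
      B <- A[sel, cand, drop = FALSE]
      Y <- backsolve(U, backsolve(U, B, transpose = TRUE))
      schur <- dA[cand] - colSums(B * Y)
      btw <- drop(crossprod(B, w))
      btv <- drop(crossprod(B, v))
      gain <- (cvec[cand] - btw) * (1 - btv) / schur
      gain[schur < 1e-10] <- 0   # linearly dependent candidate adds nothing
      val <- sum(w) + gain
    }
    pick <- cand[order(-val, ids[cand])[1]]

    if (is.null(U)) {
      U <- matrix(sqrt(dA[pick]), 1L, 1L)
    } else {
      a <- A[sel, pick]
      l <- backsolve(U, a, transpose = TRUE)
      dd <- max(dA[pick] - sum(l^2), 1e-10)
      U <- rbind(cbind(U, l), c(rep(0, length(sel)), sqrt(dd)))
    }
    sel <- c(sel, pick)
    w <- drop(chol_solve(U, cvec[sel]))
    v <- drop(chol_solve(U, rep(1, length(sel))))
    sum_trace[step] <- sum(w)
    if (step %in% sizes) {
      snapshots[[as.character(step)]] <- list(
        ids = ids[sel], p = stats::setNames(w, ids[sel]), sum_p = sum(w))
    }
  }
  structure(list(selected = ids[sel], sum_p = sum_trace,
                 snapshots = snapshots, sizes = sizes),
            class = "gene_pool_result")
}

#' Random reference sets (baseline)
#'
#' @param ids candidate animal ids.
#' @param size reference set size.
#' @param n_replicates number of independent draws.
#' @param seed RNG seed.
#' @return A list of `n_replicates` character vectors, each a uniform
#'   draw of `size` ids without replacement.
#' @export
random_select <- function(ids, size, n_replicates = 10L, seed = 1L) {
  stopifnot(size <= length(ids))
  set.seed(seed)
  lapply(seq_len(n_replicates), function(i) sample(ids, size))
}

#' Count reference relatives of each validation animal
#'
#' For every validation animal, counts reference animals whose pedigree
#' relationship falls in each of the bins `[0.50, Inf)`, `[0.25, 0.50)`,
#' `[0.125, 0.25)` and `[0.0625, 0.125)` (lower-closed, upper-open), and
#' flags the presence of a close relative (relationship strictly above
#' `close_threshold`, default 0.12).
#'
#' @param A numerator relationship matrix.
#' @param reference,validation disjoint id sets.
#' @param close_threshold close-relative threshold.
#' @return A data.frame with one row per validation animal: bin counts,
#'   `n_close` and `has_close`.
#' @export
relatives_profile <- function(A, reference, validation,
                              close_threshold = 0.12) {
  stopifnot(!any(reference %in% validation))
  R <- A[validation, reference, drop = FALSE]
  out <- data.frame(
    animal = validation,
    n_r_ge_0.50 = rowSums(R >= 0.50),
    n_r_0.25_0.50 = rowSums(R >= 0.25 & R < 0.50),
    n_r_0.125_0.25 = rowSums(R >= 0.125 & R < 0.25),
    n_r_0.0625_0.125 = rowSums(R >= 0.0625 & R < 0.125),
    n_close = rowSums(R > close_threshold),
    stringsAsFactors = FALSE
  )
  out$has_close <- out$n_close > 0L
  rownames(out) <- NULL
  out
}
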