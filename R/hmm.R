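## Li-Stephens haplotype-copying HMM.
##
## Hidden state = which of K reference haplotypes the query haplotype is
## currently copying. Between sites separated by d bp the state jumps with
## probability theta = 1 - exp(-rho * d), landing uniformly on one of the
## K haplotypes (self included); emissions match the observed allele with
## probability 1 - eps. All haplotypes of a batch share the transition
## structure, so forward/backward run as H x K matrix recursions.

ls_emission <- function(obs, ref_alleles, eps) {
  M <- outer(obs, ref_alleles, "==")     # H x K, NA where obs missing
  E <- eps + (1 - 2 * eps) * M
  E[is.na(E)] <- 1                       # missing observation: uninformative
  E
}

normalize_rows <- function(M) {
  s <- rowSums(M)
  s[s <= 0] <- 1
  M / s
}

## Batch forward-backward over the typed sites.
## O: H x T observed alleles (0/1/NA); R: K x T reference alleles;
## pos: typed positions. Returns per-site lists of alpha (filtered,
## includes site emission), and X = E * beta (emission-weighted backward),
## which is what interval interpolation needs.
ls_forward_backward <- function(O, R, pos, rho, eps) {
  K <- nrow(R)
  H <- nrow(O)
  Tt <- ncol(O)
  eps <- max(eps, 1e-12)
  theta <- if (Tt > 1L) 1 - exp(-rho * diff(pos)) else numeric(0)

  E <- lapply(seq_len(Tt), function(t) ls_emission(O[, t], R[, t], eps))
  Al <- vector("list", Tt)
  Al[[1L]] <- normalize_rows(E[[1L]] / K)
  if (Tt > 1L) {
    for (t in 2:Tt) {
      pred <- (1 - theta[t - 1L]) * Al[[t - 1L]] + theta[t - 1L] / K
      Al[[t]] <- normalize_rows(pred * E[[t]])
    }
  }
  X <- vector("list", Tt)                # E_t * beta_t, row-normalized
  Be <- matrix(1 / K, H, K)
  X[[Tt]] <- normalize_rows(E[[Tt]] * Be)
  if (Tt > 1L) {
    for (t in (Tt - 1L):1L) {
      x_next <- X[[t + 1L]]
      Be <- (1 - theta[t]) * x_next + (theta[t] / K) * rowSums(x_next)
      X[[t]] <- normalize_rows(E[[t]] * Be)
    }
  }
  list(alpha = Al, x = X, theta = theta, K = K, H = H, Tt = Tt)
}

## Posterior over states at a typed site t: alpha_t already contains the
## emission at t; X_t = E_t * beta_t would double-count it, so combine
## alpha_t with beta_t = X_t / E_t implicitly via alpha * X / E.
ls_posterior_typed <- function(fb, E_t, t) {
  normalize_rows(fb$alpha[[t]] * fb$x[[t]] / E_t)
}

#' Li-Stephens state posterior for one haplotype (reference oracle surface)
#'
#' Exact forward-backward state posteriors of the haplotype-copying HMM at
#' each typed site. Primarily exposed so the recursion can be checked
#' against independent enumeration of all state paths.
#'
#' @param obs observed alleles (0/1, `NA` = missing) at the typed sites.
#' @param ref K x T matrix of reference haplotype alleles.
#' @param pos positions (bp) of the typed sites, increasing.
#' @param rho per-bp switch intensity of the copying process.
#' @param eps allele mismatch (mutation/genotyping error) probability.
#' @return T x K matrix of posterior state probabilities (rows sum to 1).
#' @export
ls_posterior <- function(obs, ref, pos, rho, eps) {
  stopifnot(length(obs) == ncol(ref), length(pos) == ncol(ref),
            !is.unsorted(pos))
  if (nrow(ref) < 2L) stop("at least two reference haplotypes required")
  O <- matrix(obs, nrow = 1L)
  fb <- ls_forward_backward(O, ref, pos, rho, eps)
  eps <- max(eps, 1e-12)
  out <- t(vapply(seq_len(fb$Tt), function(t) {
    E_t <- ls_emission(O[, t], ref[, t], eps)
    drop(ls_posterior_typed(fb, E_t, t))
  }, numeric(nrow(ref))))
  out
}

## Dosage of every site of a chromosome for a batch of haplotypes.
## typed: logical over sites; obs alleles given at typed sites only.
## Returns H x n_sites haploid dosages in [0, 1].
ls_haploid_dosage <- function(O_typed, R_all, typed, pos_all, rho, eps) {
  K <- nrow(R_all)
  H <- nrow(O_typed)
  n <- length(typed)
  t_idx <- which(typed)
  Tt <- length(t_idx)
  dos <- matrix(NA_real_, H, n)

  if (Tt == 0L) {                        # no anchors: population mean
    dos[] <- matrix(colMeans(R_all), H, n, byrow = TRUE)
    return(dos)
  }
  R_typed <- R_all[, t_idx, drop = FALSE]
  pos_t <- pos_all[t_idx]
  fb <- ls_forward_backward(O_typed, R_typed, pos_t, rho, eps)
  eps2 <- max(eps, 1e-12)

  post_at <- function(gamma, site) drop(gamma %*% R_all[, site])

  ## typed sites: copy the observation; fill missing from the posterior
  for (tt in seq_len(Tt)) {
    site <- t_idx[tt]
    obs <- O_typed[, tt]
    dos[, site] <- obs
    if (anyNA(obs)) {
      E_t <- ls_emission(obs, R_typed[, tt], eps2)
      gamma <- ls_posterior_typed(fb, E_t, tt)
      miss <- is.na(obs)
      dos[miss, site] <- post_at(gamma, site)[miss]
    }
  }
  ## untyped sites strictly before the first anchor
  before <- which(!typed & seq_len(n) < t_idx[1L])
  for (site in before) {
    th <- 1 - exp(-rho * (pos_t[1L] - pos_all[site]))
    x1 <- fb$x[[1L]]
    gamma <- normalize_rows((1 - th) * x1 + (th / K) * rowSums(x1))
    dos[, site] <- post_at(gamma, site)
  }
  ## untyped sites after the last anchor
  after <- which(!typed & seq_len(n) > t_idx[Tt])
  for (site in after) {
    th <- 1 - exp(-rho * (pos_all[site] - pos_t[Tt]))
    gamma <- (1 - th) * fb$alpha[[Tt]] + th / K
    dos[, site] <- post_at(gamma, site)
  }
  ## interior untyped sites: forward from the left anchor, backward from
  ## the right anchor, both through the uniform-jump kernel
  if (Tt > 1L) {
    for (tt in seq_len(Tt - 1L)) {
      inner <- which(!typed & seq_len(n) > t_idx[tt] &
                       seq_len(n) < t_idx[tt + 1L])
      if (!length(inner)) next
      a <- fb$alpha[[tt]]
      x_next <- fb$x[[tt + 1L]]
      rx <- rowSums(x_next)
      for (site in inner) {
        th1 <- 1 - exp(-rho * (pos_all[site] - pos_t[tt]))
        th2 <- 1 - exp(-rho * (pos_t[tt + 1L] - pos_all[site]))
        f <- (1 - th1) * a + th1 / K
        b <- (1 - th2) * x_next + (th2 / K) * rx
        gamma <- normalize_rows(f * b)
        dos[, site] <- post_at(gamma, site)
      }
    }
  }
  dos
}
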