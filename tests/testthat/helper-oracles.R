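## Independent oracles used across the suite. These deliberately use the
## slowest, most literal formulation of each quantity so they stay
## independent of the package's optimized code paths.

## Monte-Carlo IBD oracle for additive relationships: drop unique founder
## allele labels through the pedigree at n_loci independent loci and count
## identical-by-descent allele pairs. A_ij = E[#IBD pairs] / 2.
ibd_relationship_oracle <- function(ped, n_loci = 2000L, seed = 1L) {
  set.seed(seed)
  ped <- order_pedigree(ped)
  ids <- ped$animal
  n <- length(ids)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  lab1 <- matrix(0L, n, n_loci)
  lab2 <- matrix(0L, n, n_loci)
  nxt <- 1L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      lab1[i, ] <- nxt
      nxt <- nxt + 1L
    } else {
      pick <- stats::runif(n_loci) < 0.5
      lab1[i, ] <- ifelse(pick, lab1[si[i], ], lab2[si[i], ])
    }
    if (is.na(di[i])) {
      lab2[i, ] <- nxt
      nxt <- nxt + 1L
    } else {
      pick <- stats::runif(n_loci) < 0.5
      lab2[i, ] <- ifelse(pick, lab1[di[i], ], lab2[di[i], ])
    }
  }
  A_hat <- matrix(0, n, n, dimnames = list(ids, ids))
  A_se <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (lab1[i, ] == lab1[j, ]) + (lab1[i, ] == lab2[j, ]) +
             (lab2[i, ] == lab1[j, ]) + (lab2[i, ] == lab2[j, ])
      vals <- ibd / 2
      A_hat[i, j] <- A_hat[j, i] <- mean(vals)
      A_se[i, j] <- A_se[j, i] <- stats::sd(vals) / sqrt(n_loci)
    }
  }
  list(A = A_hat, se = A_se)
}

## Exhaustive path enumeration for the haplotype-copying HMM posterior.
enum_ls_posterior <- function(obs, ref, pos, rho, eps) {
  K <- nrow(ref)
  Tt <- ncol(ref)
  theta <- 1 - exp(-rho * diff(pos))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tt)))
  probs <- apply(paths, 1L, function(z) {
    p <- 1 / K
    if (Tt > 1L) {
      for (t in 2:Tt) {
        p <- p * ((1 - theta[t - 1L]) * (z[t] == z[t - 1L]) +
                    theta[t - 1L] / K)
      }
    }
    for (t in seq_len(Tt)) {
      if (!is.na(obs[t])) {
        p <- p * if (ref[z[t], t] == obs[t]) 1 - eps else eps
      }
    }
    p
  })
  gamma <- matrix(0, Tt, K)
  for (t in seq_len(Tt)) {
    for (k in seq_len(K)) {
      gamma[t, k] <- sum(probs[paths[, t] == k])
    }
  }
  gamma / rowSums(gamma)
}

## Literal double-loop reimplementation of the segment rule.
brute_force_misplaced <- function(error_prop, map, segment_bp = 5e5,
                                  err_thresh = 0.10, count_thresh = 10L) {
  flagged <- character(0)
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    segs <- unique((sub$pos - 1L) %/% segment_bp)
    for (s in segs) {
      in_seg <- sub[(sub$pos - 1L) %/% segment_bp == s, , drop = FALSE]
      err <- error_prop[in_seg$snp_id]
      high <- in_seg$snp_id[!is.na(err) & err > err_thresh]
      if (length(high) > count_thresh) {
        flagged <- c(flagged, in_seg$snp_id)
      } else {
        flagged <- c(flagged, high)
      }
    }
  }
  sort(flagged)
}

## small star pedigree: one sire, k unrelated dams, k offspring
star_pedigree <- function(k) {
  pedigree(
    animal = c("SIRE", paste0("DAM", 1:k), paste0("OFF", 1:k)),
    sire = c("0", rep("0", k), rep("SIRE", k)),
    dam = c("0", rep("0", k), paste0("DAM", 1:k)),
    birth_year = c(2000L, rep(2000L, k), rep(2002L, k))
  )
}

## genotype matrix at Hardy-Weinberg proportions with given allele_b freqs
hwe_genotypes <- function(n_animals, freqs, prefix = "an", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- vapply(freqs, function(p) stats::rbinom(n_animals, 2L, p),
              integer(n_animals))
  dimnames(g) <- list(sprintf("%s%03d", prefix, seq_len(n_animals)),
                      names(freqs) %||% sprintf("s%04d", seq_along(freqs)))
  g
}

## default small population used by several module tests
tiny_population <- function(seed = 11L, ...) {
  args <- list(n_sires = 4L, offspring_per_sire = 8L,
               n_generations = 2L, n_chromosomes = 2L,
               n_snps_per_chrom = 150L, panel_every_k = 10L,
               n_founder_haplotypes = 20L, missing_rate = 0,
               geno_error_rate = 0, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_population(do.call(sim_config, args))
}
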