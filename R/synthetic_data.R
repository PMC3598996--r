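#' Simulation configuration for a pedigreed SNP-genotype population
#'
#' Defines a synthetic population shaped like an artificial-insemination
#' cattle breeding scheme: few sires with large paternal half-sib families,
#' founder dams that are simulated but (by default) not genotyped, dense SNP
#' maps with distance-decaying linkage disequilibrium, and a lower-density
#' panel taken as every k-th SNP of the high-density map.
#'
#' @param n_founder_haplotypes size of the founder haplotype pool that seeds
#'   the population (each founder draws two haplotypes from it).
#' @param n_sires number of sires per generation.
#' @param offspring_per_sire paternal half-sib family size.
#' @param n_generations number of offspring generations.
#' @param n_chromosomes number of independently simulated chromosomes.
#' @param n_snps_per_chrom SNP per chromosome on the high-density map.
#' @param hd_spacing_bp mean spacing between adjacent high-density SNP (bp).
#' @param chrom_length_bp chromosome length in bp; defaults to
#'   `n_snps_per_chrom * hd_spacing_bp`.
#' @param panel_every_k every k-th SNP is flagged as low-density panel
#'   member (k >= 2).
#' @param n_ancestral_haplotypes number of deep ancestral haplotypes the
#'   founder pool is a mosaic of; controls haplotype diversity.
#' @param mosaic_switch_rate per-bp probability that a founder haplotype
#'   switches to another ancestral haplotype; its inverse sets the mean
#'   ancestral segment length, hence the range of founder LD.
#' @param recomb_rate_per_bp recombination rate in Morgan per bp (Haldane,
#'   no interference). The default gives the compact simulated chromosome
#'   a genetic length of about 1 Morgan — the per-chromosome crossover
#'   count of the real cattle chromosomes it stands in for — rather than
#'   the literal per-bp cattle rate, which on a few-Mb toy chromosome
#'   would yield essentially unrecombined, chromosome-length haplotypes.
#' @param geno_error_rate probability that an observed genotype is mis-typed
#'   (uniformly to one of the two other codes).
#' @param missing_rate probability that an observed genotype is missing.
#' @param n_relocated_snps number of SNP whose map position is scrambled.
#' @param genotype_dams if `FALSE` (default) founder dams are pedigree-only,
#'   mirroring bull-only genotyping panels.
#' @param seed master RNG seed; equal seeds give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founder_haplotypes = 40L,
                       n_sires = 10L,
                       offspring_per_sire = 20L,
                       n_generations = 3L,
                       n_chromosomes = 2L,
                       n_snps_per_chrom = 1000L,
                       hd_spacing_bp = 4000,
                       chrom_length_bp = NULL,
                       panel_every_k = 15L,
                       n_ancestral_haplotypes = 8L,
                       mosaic_switch_rate = 2e-6,
                       recomb_rate_per_bp = 2.5e-7,
                       geno_error_rate = 0.005,
                       missing_rate = 0.01,
                       n_relocated_snps = 0L,
                       genotype_dams = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    n_sires = as.integer(n_sires),
    offspring_per_sire = as.integer(offspring_per_sire),
    n_generations = as.integer(n_generations),
    n_chromosomes = as.integer(n_chromosomes),
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    hd_spacing_bp = as.numeric(hd_spacing_bp),
    chrom_length_bp = as.numeric(chrom_length_bp %||%
                                   (n_snps_per_chrom * hd_spacing_bp)),
    panel_every_k = as.integer(panel_every_k),
    n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
    mosaic_switch_rate = as.numeric(mosaic_switch_rate),
    recomb_rate_per_bp = as.numeric(recomb_rate_per_bp),
    geno_error_rate = as.numeric(geno_error_rate),
    missing_rate = as.numeric(missing_rate),
    n_relocated_snps = as.integer(n_relocated_snps),
    genotype_dams = isTRUE(genotype_dams),
    seed = as.integer(seed)
  )
  counts <- c("n_founder_haplotypes", "n_sires", "offspring_per_sire",
              "n_generations", "n_chromosomes", "n_snps_per_chrom",
              "n_ancestral_haplotypes")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop(f, " must be a positive count")
  }
  rates <- c("mosaic_switch_rate", "geno_error_rate", "missing_rate")
  for (f in rates) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$recomb_rate_per_bp < 0) stop("recomb_rate_per_bp must be >= 0")
  if (cfg$panel_every_k < 2L) stop("panel_every_k must be >= 2")
  if (cfg$n_relocated_snps < 0L) stop("n_relocated_snps must be >= 0")
  if (cfg$chrom_length_bp < cfg$n_snps_per_chrom) {
    stop("chrom_length_bp too short for the requested SNP count")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a half-sib breeding pedigree with maternal grand-sire structure
#'
#' Generation 0 consists of `n_sires` founder sires. In every generation
#' each current sire is mated to `offspring_per_sire` distinct dams,
#' producing paternal half-sib families; the next generation's sires are
#' drawn from the current offspring. First-generation dams are founders;
#' from the second generation on each dam is herself a daughter of a sire
#' of the previous generation (her maternal grand-sire, avoiding the
#' mating sire) and a founder granddam — the paternal half-sib plus
#' maternal grand-sire family structure of AI cattle breeding, in which
#' the gene pool concentrates in a limited set of key ancestors. Founders
#' have unknown parents and every non-founder's parents appear earlier in
#' the record order.
#'
#' @param cfg a [sim_config()].
#' @return A [pedigree()] table.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "pedigree"))
  y0 <- 1990L
  sires <- sprintf("S%03d", seq_len(cfg$n_sires))
  rows <- data.frame(animal = sires, sire = "0", dam = "0",
                     birth_year = y0, stringsAsFactors = FALSE)
  current <- sires
  previous <- sires
  for (g in seq_len(cfg$n_generations)) {
    offspring <- character(0)
    for (s in current) {
      for (j in seq_len(cfg$offspring_per_sire)) {
        dam <- sprintf("D%d_%s_%02d", g, s, j)
        off <- sprintf("A%d_%s_%02d", g, s, j)
        if (g == 1L || length(setdiff(previous, s)) == 0L) {
          rows <- rbind(rows,
            data.frame(animal = dam, sire = "0", dam = "0",
                       birth_year = y0 + 2L * (g - 1L),
                       stringsAsFactors = FALSE))
        } else {
          mgs <- sample(setdiff(previous, s), 1L)
          granddam <- sprintf("GD%d_%s_%02d", g, s, j)
          rows <- rbind(rows,
            data.frame(animal = granddam, sire = "0", dam = "0",
                       birth_year = y0 + 2L * (g - 2L),
                       stringsAsFactors = FALSE),
            data.frame(animal = dam, sire = mgs, dam = granddam,
                       birth_year = y0 + 2L * (g - 1L),
                       stringsAsFactors = FALSE))
        }
        rows <- rbind(rows,
          data.frame(animal = off, sire = s, dam = dam,
                     birth_year = y0 + 2L * g, stringsAsFactors = FALSE))
        offspring <- c(offspring, off)
      }
    }
    previous <- current
    current <- sample(offspring, cfg$n_sires)
  }
  pedigree(rows$animal, rows$sire, rows$dam, rows$birth_year)
}

#' Simulate a founder haplotype pool with distance-decaying LD
#'
#' Each founder haplotype is a mosaic over a small set of ancestral
#' haplotypes: along the chromosome the ancestral origin switches with
#' per-bp probability `mosaic_switch_rate`, so nearby SNP share an origin
#' (high r-squared) and distant SNP do not. Marker positions and the
#' low-density panel flags are generated here too.
#'
#' @param cfg a [sim_config()].
#' @param ancestral optional list (one matrix per chromosome,
#'   `n_ancestral_haplotypes` x `n_snps_per_chrom` of 0/1 alleles)
#'   overriding the randomly drawn ancestral haplotypes.
#' @return A list of class `founder_pool` with elements `map` (a
#'   [marker_map()]), `haplotypes` and `ancestral` (per chromosome,
#'   matrices of 0/1 alleles, one row per haplotype).
#' @export
simulate_founder_haplotypes <- function(cfg, ancestral = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "founders"))
  maps <- list()
  haps <- list()
  ancs <- list()
  for (ch in seq_len(cfg$n_chromosomes)) {
    n <- cfg$n_snps_per_chrom
    ## jittered grid: dense genotyping arrays are designed for even
    ## coverage, so spacing is mean +/- jitter rather than a memoryless
    ## draw that would open multi-anchor gaps no real chip has
    step <- cfg$chrom_length_bp / n
    pos <- round((seq_len(n) - 0.5) * step +
                   stats::runif(n, -0.45, 0.45) * step)
    pos <- pmin(pmax(pos, 1), cfg$chrom_length_bp)
    if (any(diff(pos) <= 0)) {            # guard for very dense maps
      pos <- cumsum(pmax(diff(c(0, pos)), 1))
    }
    pos <- as.integer(pos)
    ids <- sprintf("snp%d_%05d", ch, seq_len(n))
    maps[[ch]] <- data.frame(
      snp_id = ids, chrom = as.character(ch), pos = pos,
      allele_a = "A", allele_b = "B",
      in_panel = FALSE,
      stringsAsFactors = FALSE
    )
    if (is.null(ancestral)) {
      p_anc <- stats::runif(n, 0.05, 0.95)
      anc <- matrix(stats::rbinom(cfg$n_ancestral_haplotypes * n, 1L,
                                  rep(p_anc,
                                      each = cfg$n_ancestral_haplotypes)),
                    nrow = cfg$n_ancestral_haplotypes)
    } else {
      anc <- ancestral[[ch]]
      stopifnot(nrow(anc) == cfg$n_ancestral_haplotypes, ncol(anc) == n)
    }
    q_switch <- 1 - exp(-cfg$mosaic_switch_rate * diff(pos))
    pool <- matrix(0L, cfg$n_founder_haplotypes, n)
    for (h in seq_len(cfg$n_founder_haplotypes)) {
      sw <- stats::runif(n - 1L) < q_switch
      segment <- cumsum(c(TRUE, sw))
      origin <- sample.int(cfg$n_ancestral_haplotypes, max(segment),
                           replace = TRUE)
      path <- origin[segment]
      pool[h, ] <- anc[cbind(path, seq_len(n))]
    }
    colnames(pool) <- ids
    colnames(anc) <- ids
    ## low-density panel: one SNP per block of k, the most polymorphic of
    ## the block (medium-density chips are MAF-optimised, so their content
    ## survives downstream frequency filters), plus a terminal anchor so
    ## no chromosome end is left untyped
    pf <- colMeans(pool)
    maf_pool <- pmin(pf, 1 - pf)
    block <- (seq_len(n) - 1L) %/% cfg$panel_every_k
    picks <- vapply(split(seq_len(n), block), function(ix) {
      ix[which.max(maf_pool[ix])]
    }, integer(1))
    ## terminal anchors: both chromosome ends get a typed SNP within half
    ## a block, so no end is left with a long untyped overhang
    half <- max(1L, cfg$panel_every_k %/% 2L)
    head_ix <- seq_len(min(half, n))
    tail_ix <- seq.int(max(1L, n - half + 1L), n)
    picks <- unique(c(picks,
                      head_ix[which.max(maf_pool[head_ix])],
                      tail_ix[which.max(maf_pool[tail_ix])]))
    maps[[ch]]$in_panel[picks] <- TRUE
    haps[[as.character(ch)]] <- pool
    ancs[[as.character(ch)]] <- anc
  }
  map <- sort_map(do.call(rbind, maps))
  structure(list(map = map, haplotypes = haps, ancestral = ancs),
            class = "founder_pool")
}

## one meiosis: recombinant gamete under Haldane's no-interference model
meiosis <- function(h1, h2, pos, rate_per_bp) {
  n <- length(pos)
  span <- pos[n] - pos[1]
  nx <- stats::rpois(1L, rate_per_bp * span)
  start <- sample.int(2L, 1L)
  if (nx == 0L) {
    return(if (start == 1L) h1 else h2)
  }
  xo <- sort(stats::runif(nx, pos[1], pos[n]))
  k <- findInterval(pos, xo)
  use1 <- ((k + start) %% 2L) == 1L
  ifelse(use1, h1, h2)
}

#' Drop founder haplotypes through a pedigree
#'
#' Founders draw two haplotypes from the founder pool; every non-founder
#' inherits one recombinant gamete per parent, with crossovers placed by a
#' Poisson (Haldane, no-interference) process at `recomb_rate_per_bp`.
#' Genotype codes are the per-SNP sum of the two haplotype alleles.
#'
#' @param ped a [pedigree()] (must be orderable; a cycle is an error).
#' @param pool a `founder_pool` from [simulate_founder_haplotypes()].
#' @param cfg the [sim_config()] used to build both.
#' @return A list of class `truth_set`: `genotypes` (error-free, complete
#'   matrix for genotyped animals), `haplotypes` (list `h1`, `h2` of phased
#'   allele matrices, same dimnames), `map`, `pedigree`, `genotyped_ids`
#'   and `relocated_snp_ids` (empty here).
#' @export
gene_drop <- function(ped, pool, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(pool, "founder_pool"))
  set.seed(derive_seed(cfg$seed, "genedrop"))
  ped <- order_pedigree(ped)
  ids <- ped$animal
  n_anim <- length(ids)
  founder <- is_founder(ped)
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  map <- pool$map

  h1_all <- list()
  h2_all <- list()
  for (ch in names(pool$haplotypes)) {
    hp <- pool$haplotypes[[ch]]
    snps <- colnames(hp)
    pos <- map$pos[match(snps, map$snp_id)]
    H1 <- matrix(0L, n_anim, ncol(hp), dimnames = list(ids, snps))
    H2 <- H1
    for (i in seq_len(n_anim)) {
      if (founder[i]) {
        k <- sample.int(nrow(hp), 2L, replace = TRUE)
        H1[i, ] <- hp[k[1L], ]
        H2[i, ] <- hp[k[2L], ]
      } else {
        H1[i, ] <- meiosis(H1[si[i], ], H2[si[i], ], pos,
                           cfg$recomb_rate_per_bp)
        H2[i, ] <- meiosis(H1[di[i], ], H2[di[i], ], pos,
                           cfg$recomb_rate_per_bp)
      }
    }
    h1_all[[ch]] <- H1
    h2_all[[ch]] <- H2
  }
  h1 <- do.call(cbind, h1_all)[, map$snp_id, drop = FALSE]
  h2 <- do.call(cbind, h2_all)[, map$snp_id, drop = FALSE]

  ## bull-only genotyping: any animal used as a dam is pedigree-only
  genotyped <- if (cfg$genotype_dams) {
    ids
  } else {
    ids[!(ids %in% ped$dam) & (!founder | ids %in% ped$sire)]
  }
  structure(list(
    genotypes = h1[genotyped, , drop = FALSE] + h2[genotyped, , drop = FALSE],
    haplotypes = list(h1 = h1[genotyped, , drop = FALSE],
                      h2 = h2[genotyped, , drop = FALSE]),
    map = map,
    pedigree = ped,
    genotyped_ids = genotyped,
    relocated_snp_ids = character(0)
  ), class = "truth_set")
}

#' Degrade a truth set into observed genotypes
#'
#' Independently sets each genotype missing with `missing_rate` and
#' mis-types each surviving genotype with `geno_error_rate` (uniformly to
#' one of the two other codes).
#'
#' @param truth a `truth_set` from [gene_drop()].
#' @param cfg the [sim_config()].
#' @return A genotype matrix with `NA` for missing calls.
#' @export
degrade <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_set"), inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "degrade"))
  g <- truth$genotypes
  nc <- length(g)
  miss <- stats::runif(nc) < cfg$missing_rate
  err <- stats::runif(nc) < cfg$geno_error_rate & !miss
  if (any(err)) {
    shift <- sample(c(1L, 2L), sum(err), replace = TRUE)
    g[err] <- (g[err] + shift) %% 3L
  }
  g[miss] <- NA_integer_
  g
}

#' Relocate SNP to wrong map positions
#'
#' Assigns `n` SNP new random coordinates (possibly on other chromosomes)
#' while leaving their genotype columns untouched, emulating map errors.
#' The returned map is re-sorted by (chromosome, position); realign
#' genotype columns with [align_genotypes()].
#'
#' @param map a [marker_map()].
#' @param n number of SNP to relocate (`n < nrow(map)`).
#' @param seed RNG seed.
#' @param candidate_ids optional subset of SNP ids eligible for relocation.
#' @param min_shift_bp minimum same-chromosome displacement. The default 0
#'   places SNP uniformly at random; a large value restricts injections to
#'   assembly-scale errors (distant or inter-chromosomal misplacements),
#'   the kind an imputation-error screen can reveal — misplacement over
#'   short distances is invisible to it because local LD is preserved.
#' @return A list: `map` (re-sorted), `relocated_ids`, and `original`
#'   (data.frame of the pre-relocation coordinates of the moved SNP).
#' @export
relocate_snps <- function(map, n, seed = 1L, candidate_ids = NULL,
                          min_shift_bp = 0) {
  stopifnot(n < nrow(map), n >= 0)
  if (n == 0L) {
    return(list(map = map, relocated_ids = character(0),
                original = map[0, c("snp_id", "chrom", "pos")]))
  }
  set.seed(seed)
  cand <- candidate_ids %||% map$snp_id
  stopifnot(all(cand %in% map$snp_id))
  ids <- sample(cand, n)
  idx <- match(ids, map$snp_id)
  original <- map[idx, c("snp_id", "chrom", "pos")]
  chroms <- unique(map$chrom)
  max_pos <- max(map$pos)
  taken <- paste(map$chrom, map$pos)
  for (i in idx) {
    repeat {
      new_chrom <- sample(chroms, 1L)
      new_pos <- sample.int(max_pos, 1L)
      if (paste(new_chrom, new_pos) %in% taken) next
      if (new_chrom == map$chrom[i] &&
          abs(new_pos - map$pos[i]) < min_shift_bp) next
      break
    }
    map$chrom[i] <- new_chrom
    map$pos[i] <- new_pos
    taken <- c(taken, paste(new_chrom, new_pos))
  }
  list(map = sort_map(map), relocated_ids = ids, original = original)
}

#' Simulate a complete study population
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_founder_haplotypes()], [gene_drop()], [degrade()] and (if
#' `n_relocated_snps > 0`) [relocate_snps()] on non-panel SNP.
#'
#' @param cfg a [sim_config()].
#' @return A list with `truth` (truth set), `genotypes` (degraded observed
#'   matrix, columns in map order), `map` (post-relocation if any),
#'   `pedigree`, `relocated_ids` and `relocated_original`.
#' @export
simulate_population <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  pool <- simulate_founder_haplotypes(cfg)
  truth <- gene_drop(ped, pool, cfg)
  gm <- degrade(truth, cfg)
  map <- truth$map
  relocated <- character(0)
  original <- map[0, c("snp_id", "chrom", "pos")]
  if (cfg$n_relocated_snps > 0L) {
    rel <- relocate_snps(map, cfg$n_relocated_snps,
                         seed = derive_seed(cfg$seed, "relocate"),
                         candidate_ids = map$snp_id[!map$in_panel])
    map <- rel$map
    relocated <- rel$relocated_ids
    original <- rel$original
    gm <- align_genotypes(gm, map)
    truth$relocated_snp_ids <- relocated
  }
  list(truth = truth, genotypes = align_genotypes(gm, map), map = map,
       pedigree = truth$pedigree, relocated_ids = relocated,
       relocated_original = original)
}

#' Extract phased haplotypes as a matrix of haploid rows
#'
#' @param truth a `truth_set`.
#' @param ids animals to extract (default all genotyped).
#' @return A matrix with two rows per animal (`<id>.1`, `<id>.2`) of 0/1
#'   alleles, columns in map order.
#' @export
truth_haplotypes <- function(truth, ids = NULL) {
  ids <- ids %||% rownames(truth$haplotypes$h1)
  h1 <- truth$haplotypes$h1[ids, , drop = FALSE]
  h2 <- truth$haplotypes$h2[ids, , drop = FALSE]
  out <- rbind(h1, h2)
  rownames(out) <- c(paste0(ids, ".1"), paste0(ids, ".2"))
  ## interleave so an animal's two haplotypes are adjacent
  ord <- as.vector(rbind(seq_along(ids), seq_along(ids) + length(ids)))
  out[ord, , drop = FALSE]
}
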