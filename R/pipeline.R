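#' Run the full evaluation pipeline from a config
#'
#' Orchestrates simulate -> QC -> key-animal selection -> masking ->
#' HMM imputation -> accuracy evaluation -> misplaced-SNP detection as one
#' reproducible run. Stage outputs are files inside the run directory, so
#' a re-run resumes from the first stage whose outputs are missing, and a
#' JSON manifest records seeds, dimensions and timings.
#'
#' @param config path to a YAML config, or an equivalent named list.
#'   Recognized blocks: `seed`, `run_dir`, `sim` (arguments of
#'   [sim_config()]), `qc` (arguments of [qc_config()] plus logical
#'   `enabled`), `selection` (`sizes`, `random_replicates`), `imputation`
#'   (`rho`, `eps`) and `misplaced` (`segment_bp`, `err_thresh`,
#'   `count_thresh`, `enabled`).
#' @param run_dir output directory (overrides the config entry).
#' @return Invisibly, a list with the run directory, the manifest and the
#'   accuracy summary table.
#' @export
run_pipeline <- function(config, run_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- as.integer(cfg$seed %||% 1L)
  run_dir <- run_dir %||% cfg$run_dir %||% stop("no run_dir given")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("sim", "qc", "select", "results")) {
    dir.create(file.path(run_dir, d), showWarnings = FALSE)
  }
  log_line <- function(...) message("[keyimpute] ", sprintf(...))
  timings <- list()
  stage <- function(name, outputs, fn) {
    paths <- file.path(run_dir, outputs)
    if (all(file.exists(paths))) {
      log_line("stage %-10s skipped (outputs present)", name)
      return(invisible(FALSE))
    }
    t0 <- proc.time()[["elapsed"]]
    fn()
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    log_line("stage %-10s done in %.1fs", name, timings[[name]])
    invisible(TRUE)
  }

  sim_args <- cfg$sim %||% list()
  sim_args$seed <- sim_args$seed %||% seed
  scfg <- do.call(sim_config, sim_args)
  sizes <- as.integer(cfg$selection$sizes %||% c(25L, 50L, 100L))
  rho <- cfg$imputation$rho %||% 1e-6
  eps <- cfg$imputation$eps %||% 0.002

  p <- function(...) file.path(run_dir, ...)

  ## -- simulate -------------------------------------------------------
  stage("simulate", c("sim/genotypes.vcf", "sim/map.tsv", "sim/pedigree.csv",
                      "sim/truth_genotypes.tsv", "sim/truth_h1.tsv",
                      "sim/truth_h2.tsv", "sim/relocated.tsv"), function() {
    pop <- simulate_population(scfg)
    write_vcf(pop$genotypes, pop$map, p("sim/genotypes.vcf"))
    write_marker_map(pop$map, p("sim/map.tsv"))
    write_pedigree_csv(pop$pedigree, p("sim/pedigree.csv"))
    write_genotype_tsv(pop$truth$genotypes, p("sim/truth_genotypes.tsv"))
    write_genotype_tsv(pop$truth$haplotypes$h1, p("sim/truth_h1.tsv"))
    write_genotype_tsv(pop$truth$haplotypes$h2, p("sim/truth_h2.tsv"))
    rel <- pop$relocated_original
    rel$snp_id <- as.character(rel$snp_id)
    write_report(rel, p("sim/relocated.tsv"))
  })

  ## -- qc -------------------------------------------------------------
  stage("qc", c("qc/genotypes.tsv", "qc/map.tsv", "qc/report.tsv"), function() {
    gin <- read_genotypes(p("sim/genotypes.vcf"), "vcf")
    map <- read_marker_map(p("sim/map.tsv"))
    ped <- read_pedigree_csv(p("sim/pedigree.csv"))
    qcc <- do.call(qc_config, cfg$qc[setdiff(names(cfg$qc %||% list()),
                                             "enabled")] %||% list())
    if (isFALSE(cfg$qc$enabled)) {
      res <- list(genotypes = align_genotypes(gin$genotypes, map), map = map,
                  report = data.frame(step = character(0),
                                      snps_removed = integer(0),
                                      animals_removed = integer(0)))
    } else {
      res <- run_qc(gin$genotypes, map, ped, qcc,
                    screen_relationships = FALSE)
    }
    write_genotype_tsv(res$genotypes, p("qc/genotypes.tsv"))
    write_marker_map(res$map, p("qc/map.tsv"))
    write_report(res$report, p("qc/report.tsv"))
  })

  ## -- selection ------------------------------------------------------
  stage("select", "select/keyanimals.tsv", function() {
    gm <- read_genotype_tsv(p("qc/genotypes.tsv"))
    ped <- read_pedigree_csv(p("sim/pedigree.csv"))
    A <- build_nrm(ped)
    ids <- intersect(rownames(gm), rownames(A))
    sel <- greedy_select(A[ids, ids], sizes)
    tab <- data.frame(rank = seq_along(sel$selected),
                      animal = sel$selected,
                      cum_gene_pool = sel$sum_p, stringsAsFactors = FALSE)
    write_report(tab, p("select/keyanimals.tsv"))
  })

  ## -- impute + evaluate per reference size ----------------------------
  out_files <- c("results/accuracy_summary.tsv",
                 sprintf("results/per_animal_size%d.tsv", sizes))
  stage("evaluate", out_files, function() {
    gm <- read_genotype_tsv(p("qc/genotypes.tsv"))
    map <- read_marker_map(p("qc/map.tsv"))
    ped <- read_pedigree_csv(p("sim/pedigree.csv"))
    truth <- read_genotype_tsv(p("sim/truth_genotypes.tsv"))
    h1 <- read_genotype_tsv(p("sim/truth_h1.tsv"))
    h2 <- read_genotype_tsv(p("sim/truth_h2.tsv"))
    key <- utils::read.table(p("select/keyanimals.tsv"), header = TRUE,
                             sep = "\t", colClasses = c(animal = "character"))
    truth <- truth[rownames(gm), map$snp_id, drop = FALSE]
    A <- build_nrm(ped)
    rows <- list()
    for (s in sizes) {
      reference <- key$animal[seq_len(s)]
      validation <- setdiff(rownames(gm), reference)
      sc <- make_scenario(gm, map, reference, validation)
      ref_h <- haps_matrix(h1, h2, reference, map$snp_id)
      val_h <- haps_matrix(h1, h2, validation, map$snp_id)
      res <- hmm_impute(sc$scenario, sc$genotypes, map, ref_h, val_h,
                        rho = rho, eps = eps)
      conc <- concordance(truth, res$genotypes, sc$scenario)
      per_an <- r_tg_ig(truth, res$genotypes, sc$scenario, by = "animal",
                        dosage = res$dosage)
      prof <- relatives_profile(A[rownames(gm), rownames(gm)],
                                reference, validation)
      joined <- accuracy_vs_relatives(per_an, prof)
      write_report(joined$per_animal,
                   p(sprintf("results/per_animal_size%d.tsv", s)))
      rows[[as.character(s)]] <- data.frame(
        reference_size = s, imputer = "hmm_ls",
        correct_alleles = conc$correct_alleles,
        correct_genotypes = conc$correct_genotypes,
        r_tgig_mean_animal = mean(per_an$r, na.rm = TRUE),
        residual_missing = sum(res$residual_missing))
    }
    write_report(do.call(rbind, rows), p("results/accuracy_summary.tsv"))
  })

  ## -- misplaced SNP ----------------------------------------------------
  stage("misplaced", "results/misplaced.tsv", function() {
    if (isFALSE(cfg$misplaced$enabled)) {
      write_report(data.frame(snp_id = character(0), chrom = character(0),
                              pos = integer(0), error_prop = numeric(0),
                              reason = character(0)),
                   p("results/misplaced.tsv"))
      return()
    }
    gm <- read_genotype_tsv(p("qc/genotypes.tsv"))
    map <- read_marker_map(p("qc/map.tsv"))
    truth <- read_genotype_tsv(p("sim/truth_genotypes.tsv"))
    h1 <- read_genotype_tsv(p("sim/truth_h1.tsv"))
    h2 <- read_genotype_tsv(p("sim/truth_h2.tsv"))
    key <- utils::read.table(p("select/keyanimals.tsv"), header = TRUE,
                             sep = "\t", colClasses = c(animal = "character"))
    s <- max(sizes)
    reference <- key$animal[seq_len(s)]
    validation <- setdiff(rownames(gm), reference)
    sc <- make_scenario(gm, map, reference, validation)
    res <- hmm_impute(sc$scenario, sc$genotypes, map,
                      haps_matrix(h1, h2, reference, map$snp_id),
                      haps_matrix(h1, h2, validation, map$snp_id),
                      rho = rho, eps = eps)
    truth <- truth[rownames(gm), map$snp_id, drop = FALSE]
    errs <- snp_error_proportion(truth, res$genotypes, sc$scenario)
    mp <- cfg$misplaced %||% list()
    rep <- detect_misplaced(errs, map,
                            segment_bp = mp$segment_bp %||% 5e5,
                            err_thresh = mp$err_thresh %||% 0.10,
                            count_thresh = mp$count_thresh %||% 10L)
    write_report(rep$flagged, p("results/misplaced.tsv"))
  })

  summary_tab <- utils::read.table(p("results/accuracy_summary.tsv"),
                                   header = TRUE, sep = "\t")
  manifest <- list(
    package_version = as.character(utils::packageVersion("keyimpute")),
    seed = seed,
    sizes = sizes,
    sim = unclass(scfg),
    timings = timings,
    files = list.files(run_dir, recursive = TRUE)
  )
  write_report(manifest, p("manifest.json"))
  invisible(list(run_dir = run_dir, manifest = manifest,
                 summary = summary_tab))
}

#' Interleave per-animal haplotype matrices into haploid rows
#'
#' @param h1,h2 phased allele matrices (animals x SNP).
#' @param ids animals to extract.
#' @param snp_ids column order.
#' @return Matrix with rows `<id>.1`, `<id>.2` per animal.
#' @export
haps_matrix <- function(h1, h2, ids, snp_ids) {
  out <- matrix(0L, 2L * length(ids), length(snp_ids),
                dimnames = list(as.vector(rbind(paste0(ids, ".1"),
                                                paste0(ids, ".2"))),
                                snp_ids))
  out[seq(1L, nrow(out), 2L), ] <- h1[ids, snp_ids, drop = FALSE]
  out[seq(2L, nrow(out), 2L), ] <- h2[ids, snp_ids, drop = FALSE]
  out
}
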