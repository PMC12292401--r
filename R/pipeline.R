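#' Run the full genotype-to-regions pipeline from a config
#'
#' Orchestrates the analysis stages in dependency order — input (read or
#' simulate) -> QC per profile -> structure / ROH / LD-Ne / selection
#' scans -> annotation — writing TSV/BED artifacts and a JSON manifest
#' (parameters, dimensions, checksums) into the output directory.
#' Rerunning with the same config and seed reproduces identical outputs.
#'
#' The config is a nested list (or path to a YAML file with the same
#' shape): either `simulate:` (arguments for [sim_config()]) or `input:`
#' (`ped`, `map`, `vcf`, optional `subpop`), a `seed`, an `output_dir`,
#' and an `analyses:` block with switches/parameters for `pca`,
#' `admixture` (`kmin`, `kmax`, `folds`), `roh` (detection parameters and
#' `island_threshold`), `ldne` (`window_bp`, `alpha`), `ihs`
#' (`population`), `rsb` (`pop_a`, `pop_b` — `pop_b` may list several
#' populations pooled), and `annotation` (`genes`, `gene_sets` paths).
#'
#' @param config list or YAML path.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  out_dir <- cfg$output_dir %||% stop_cs("config needs output_dir")
  seed <- as.integer(cfg$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  an <- cfg$analyses %||% list()

  # validate before any compute
  if (!is.null(an$rsb)) {
    pops <- c(an$rsb$pop_a, unlist(an$rsb$pop_b))
    if (length(unique(pops)) < 2L)
      stop_cs("rsb requires two distinct populations in the config")
  }
  if (is.null(cfg$simulate) == is.null(cfg$input))
    stop_cs("config needs exactly one of 'simulate' or 'input'")

  manifest <- list(seed = seed, stages = list(), files = list())
  t0 <- Sys.time()
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e) {
      writeLines(paste0("FAILED at stage ", name, ": ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop_cs("pipeline failed at stage '", name, "': ", conditionMessage(e))
    })
    inform(paste0("[", name, "] done"))
    res
  }

  # ---- input ----
  dat <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = seed)))
      d <- sim_dataset(sc)
      list(genotypes = d$genotypes, haplotypes = d$haplotypes, truth = d$truth,
           chrom_length_bp = sc$chrom_length_bp)
    } else {
      g <- read_ped_map(cfg$input$ped, cfg$input$map,
                        subpop_path = cfg$input$subpop)
      haps <- NULL
      if (!is.null(cfg$input$vcf)) {
        hall <- read_phased_vcf(cfg$input$vcf,
                                populations = g$samples[, c("sample_id", "population")])
        haps <- purrr::map(
          setNames(nm = unique(g$samples$population)),
          function(p) subset_haplotypes(
            hall, samples = g$samples$sample_id[g$samples$population == p]))
      }
      list(genotypes = g, haplotypes = haps, truth = NULL,
           chrom_length_bp = cfg$input$chrom_length_bp)
    }
  })
  g <- dat$genotypes
  manifest$stages$input <- list(n_samples = nrow(g$samples),
                                n_variants = nrow(g$variants))

  autosomes <- autosome_lengths_of(g, dat$chrom_length_bp)

  # ---- qc (three profiles as the analyses need them) ----
  qc <- stage("qc", {
    list(
      structure = apply_qc_quiet(g, "structure"),
      selection = apply_qc_quiet(g, "selection"),
      diversity = apply_qc_quiet(g, "diversity")
    )
  })
  for (pr in names(qc)) {
    rep <- qc[[pr]]$report
    readr::write_tsv(tidy(rep), file.path(out_dir, paste0("qc_", pr, ".tsv")))
    manifest$stages[[paste0("qc_", pr)]] <- tidy(rep)
  }

  # ---- structure ----
  if (isTRUE(an$pca) || !is.null(an$admixture)) {
    stage("structure", {
      gs <- qc$structure$genotypes
      if (isTRUE(an$pca)) {
        p <- pca_genotypes(gs, n_components = min(10, nrow(gs$samples) - 1))
        readr::write_tsv(p$scores, file.path(out_dir, "pca_scores.tsv"))
        manifest$stages$pca <- list(variance_fraction = p$variance_fraction)
      }
      if (!is.null(an$admixture)) {
        ks <- admixture_scan_k(gs, k_range = an$admixture$kmin:an$admixture$kmax,
                               folds = an$admixture$folds %||% 5, seed = seed)
        best <- attr(ks, "best_k")
        fit <- admixture_em(gs, best, seed = seed)
        readr::write_tsv(fit$Q, file.path(out_dir, "admixture_Q.tsv"))
        readr::write_tsv(ks, file.path(out_dir, "admixture_cv.tsv"))
        manifest$stages$admixture <- list(best_k = best, cv = ks)
      }
      ho <- observed_homozygosity(qc$diversity$genotypes)
      readr::write_tsv(ho, file.path(out_dir, "observed_homozygosity.tsv"))
      invisible(NULL)
    })
  }

  # ---- roh ----
  roh_segments <- NULL
  if (!is.null(an$roh)) {
    roh_segments <- stage("roh", {
      pars <- do.call(roh_params, an$roh[setdiff(names(an$roh), "island_threshold")])
      segs <- detect_roh(qc$diversity$genotypes, pars)
      fr <- froh(segs, autosomes, sample_ids = qc$diversity$genotypes$samples$sample_id)
      readr::write_tsv(segs, file.path(out_dir, "roh_segments.tsv"))
      readr::write_tsv(fr$genome, file.path(out_dir, "froh.tsv"))
      readr::write_tsv(roh_size_classes(segs), file.path(out_dir, "roh_size_classes.tsv"))
      isl <- roh_islands(segs, qc$diversity$genotypes,
                         threshold_fraction = an$roh$island_threshold %||% 0.5)
      readr::write_tsv(isl, file.path(out_dir, "roh_islands.tsv"))
      if (nrow(isl)) write_bed_intervals(isl, file.path(out_dir, "roh_islands.bed"))
      manifest$stages$roh <- list(n_segments = nrow(segs), n_islands = nrow(isl))
      list(segments = segs, islands = isl)
    })
  }

  # ---- ld / ne ----
  if (!is.null(an$ldne)) {
    stage("ldne", {
      gd <- qc$diversity$genotypes
      pairs <- pairwise_r2(gd, window_bp = an$ldne$window_bp %||% 1e6, r2_floor = 0)
      prof <- ld_decay_profile(pairs)
      ne <- estimate_ne_sved(pairs, n_samples = nrow(gd$samples),
                             alpha = an$ldne$alpha %||% 2)
      readr::write_tsv(prof, file.path(out_dir, "ld_decay.tsv"))
      readr::write_tsv(ne, file.path(out_dir, "ne_trajectory.tsv"))
      manifest$stages$ldne <- list(
        decay_distance_bp = attr(prof, "decay_distance_bp"),
        n_pairs = nrow(pairs))
      invisible(NULL)
    })
  }

  # ---- selection scans ----
  regions_all <- list()
  if (!is.null(an$ihs)) {
    if (is.null(dat$haplotypes)) stop_cs("ihs requires phased haplotypes")
    stage("ihs", {
      # scans run on the phased data restricted to the selection-QC'd set
      keep <- intersect(qc$selection$genotypes$variants$variant_id,
                        dat$haplotypes[[an$ihs$population]]$variants$variant_id)
      h <- subset_haplotypes(dat$haplotypes[[an$ihs$population]], variants = keep)
      h <- filter_haplotypes_maf(h, 0.05)
      sites <- ihs_scan(h)
      win <- window_statistics(filter(sites, !is.na(.data$ihs)), "ihs")
      win <- rank_pvalues(win, tail = "two")
      reg <- call_candidate_regions(win, statistic = "iHS")
      readr::write_tsv(sites, file.path(out_dir, "ihs_sites.tsv"))
      readr::write_tsv(win, file.path(out_dir, "ihs_windows.tsv"))
      readr::write_tsv(reg, file.path(out_dir, "ihs_regions.tsv"))
      if (nrow(reg)) write_bed_intervals(reg, file.path(out_dir, "ihs_regions.bed"))
      manifest$stages$ihs <- list(n_regions = nrow(reg))
      regions_all$ihs <- reg
    })
  }
  if (!is.null(an$rsb)) {
    if (is.null(dat$haplotypes)) stop_cs("rsb requires phased haplotypes")
    stage("rsb", {
      keep <- qc$selection$genotypes$variants$variant_id
      h1 <- subset_haplotypes(dat$haplotypes[[an$rsb$pop_a]], variants = keep)
      h2s <- purrr::map(dat$haplotypes[unlist(an$rsb$pop_b)],
                        subset_haplotypes, variants = keep)
      h2 <- if (length(h2s) == 1L) h2s[[1]] else merge_haplotype_sets(h2s)
      sites <- rsb_scan(h1, h2)
      win <- window_statistics(filter(sites, !is.na(.data$rsb)), "rsb")
      win <- rank_pvalues(win, tail = "right")
      reg <- call_candidate_regions(win, statistic = "Rsb")
      readr::write_tsv(sites, file.path(out_dir, "rsb_sites.tsv"))
      readr::write_tsv(win, file.path(out_dir, "rsb_windows.tsv"))
      readr::write_tsv(reg, file.path(out_dir, "rsb_regions.tsv"))
      if (nrow(reg)) write_bed_intervals(reg, file.path(out_dir, "rsb_regions.bed"))
      manifest$stages$rsb <- list(n_regions = nrow(reg))
      regions_all$rsb <- reg
    })
  }

  # ---- annotation ----
  if (!is.null(an$annotation)) {
    stage("annotation", {
      genes <- read_gene_intervals(an$annotation$genes)
      regions <- bind_rows(
        c(regions_all,
          if (!is.null(roh_segments)) list(islands = roh_segments$islands))
      )
      hits <- intersect_regions_genes(regions, genes)
      readr::write_tsv(hits, file.path(out_dir, "region_genes.tsv"))
      if (!is.null(an$annotation$gene_sets)) {
        sets <- read_gene_sets(an$annotation$gene_sets)
        universe <- unique(genes$gene_id[is_autosome_label(genes$chromosome) &
                                           genes$chromosome %in% unique(g$variants$chromosome)])
        enr <- hypergeometric_enrichment(
          intersect(unique(hits$gene_id), universe), sets, universe)
        readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
        manifest$stages$annotation <- list(n_genes = length(unique(hits$gene_id)),
                                           n_terms = nrow(enr))
      }
      invisible(NULL)
    })
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- purrr::map(setNames(files, basename(files)),
                               ~ unname(tools::md5sum(.x)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

apply_qc_quiet <- function(g, profile) {
  suppressWarnings(apply_qc(g, profile))
}

# chromosome lengths used for F_ROH denominators: simulated length when
# known, otherwise the last SNP position per chromosome
autosome_lengths_of <- function(g, chrom_length_bp = NULL) {
  chroms <- unique(g$variants$chromosome)
  if (!is.null(chrom_length_bp))
    return(tibble(chromosome = chroms, length_bp = chrom_length_bp))
  g$variants %>%
    group_by(chromosome = .data$chromosome) %>%
    summarise(length_bp = max(.data$position_bp), .groups = "drop")
}
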