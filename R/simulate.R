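#' Simulation configuration for structured goat-like SNP data
#'
#' Describes a Balding-Nichols mosaic-of-founders simulation: an ancestral
#' allele-frequency spectrum, per-population differentiated frequencies,
#' founder haplotype panels, and sample haplotypes built as founder mosaics
#' whose switch process generates LD that decays with physical distance.
#' Populations can carry village-level substructure and per-population
#' autozygosity targets; selective sweeps can be planted on top.
#'
#' The defaults emulate a three-breed SNP-array study design: one isolated
#' mountain breed with three village subgroups and elevated autozygosity
#' (F_ROH target 0.16) plus two lowland comparator breeds (targets 0.05 and
#' 0.08), with chip-like marker density (~50 kb inter-SNP gaps).
#'
#' @param n_chromosomes number of autosomes to simulate.
#' @param snps_per_chromosome markers per autosome.
#' @param chrom_length_bp autosome length in bp.
#' @param n_founders founder haplotypes per (sub)population panel.
#' @param switch_rate_per_bp per-bp founder switch rate; between adjacent
#'   SNPs a haplotype switches founder with probability
#'   `1 - exp(-rate * gap_bp)`.
#' @param populations list of population specs as from [sim_population_spec()].
#' @param sweeps list of sweep specs as from [sim_sweep_spec()].
#' @param autozygosity_min_bp,autozygosity_max_bp bounds of planted
#'   autozygous segment lengths (uniform draw).
#' @param seed integer seed for the whole generation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4,
                       snps_per_chromosome = 1000,
                       chrom_length_bp = 50e6,
                       n_founders = 30,
                       switch_rate_per_bp = 5e-7,
                       populations = default_populations(),
                       sweeps = list(),
                       autozygosity_min_bp = 1e6,
                       autozygosity_max_bp = 8e6,
                       seed = 1L) {
  stopifnot(n_chromosomes >= 1, snps_per_chromosome >= 2, chrom_length_bp >= 1,
            n_founders >= 2, switch_rate_per_bp >= 0)
  for (p in populations) {
    if (!(p$fst > 0 && p$fst < 1))
      stop_cs("population '", p$name, "': fst must lie in (0,1)")
    if (!(p$autozygosity_target >= 0 && p$autozygosity_target <= 0.95))
      stop_cs("population '", p$name, "': autozygosity_target must lie in [0, 0.95]")
    if (p$n_samples < 1) stop_cs("population '", p$name, "': n_samples must be >= 1")
  }
  for (s in sweeps) {
    if (!(s$carrier_fraction > 0 && s$carrier_fraction <= 1))
      stop_cs("sweep carrier_fraction must lie in (0, 1]")
    if (s$core_position_bp < 1 || s$core_position_bp > chrom_length_bp)
      stop_cs("sweep core_position_bp outside chromosome bounds")
  }
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      snps_per_chromosome = as.integer(snps_per_chromosome),
      chrom_length_bp = chrom_length_bp,
      n_founders = as.integer(n_founders),
      switch_rate_per_bp = switch_rate_per_bp,
      populations = populations,
      sweeps = sweeps,
      autozygosity_min_bp = autozygosity_min_bp,
      autozygosity_max_bp = autozygosity_max_bp,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param name population label.
#' @param n_samples diploid samples to draw.
#' @param fst Balding-Nichols differentiation from the ancestral pool, in (0,1).
#' @param autozygosity_target expected F_ROH planted into this population.
#' @param subpopulations optional named integer vector of village sample
#'   sizes (must sum to `n_samples`); villages get weakly differentiated
#'   founder panels (Balding-Nichols around the population frequencies).
#' @param village_fst differentiation of village panels around the
#'   population frequencies.
#' @export
sim_population_spec <- function(name, n_samples, fst, autozygosity_target = 0,
                                subpopulations = NULL, village_fst = 0.02) {
  if (!is.null(subpopulations) && sum(subpopulations) != n_samples)
    stop_cs("subpopulation sizes must sum to n_samples")
  list(name = name, n_samples = as.integer(n_samples), fst = fst,
       autozygosity_target = autozygosity_target,
       subpopulations = subpopulations, village_fst = village_fst)
}

#' @rdname sim_config
#' @param population population the sweep is planted in.
#' @param chromosome chromosome label (e.g. "1").
#' @param core_position_bp physical position of the sweep core.
#' @param carrier_fraction fraction of haplotypes carrying the swept
#'   haplotype, in (0,1].
#' @param mean_tract_bp mean one-sided length of the homogenized tract
#'   (exponential per haplotype and side).
#' @export
sim_sweep_spec <- function(population, chromosome, core_position_bp,
                           carrier_fraction = 0.8, mean_tract_bp = 1e6) {
  list(population = population, chromosome = as.character(chromosome),
       core_position_bp = core_position_bp,
       carrier_fraction = carrier_fraction, mean_tract_bp = mean_tract_bp)
}

# study-like default design: 3 differentiated populations, the first with
# three village subgroups and strong autozygosity
default_populations <- function() {
  list(
    sim_population_spec("mountain", 76, fst = 0.08, autozygosity_target = 0.16,
                        subpopulations = c(village1 = 32, village2 = 19, village3 = 25)),
    sim_population_spec("desert_a", 40, fst = 0.08, autozygosity_target = 0.05),
    sim_population_spec("desert_b", 30, fst = 0.08, autozygosity_target = 0.08)
  )
}

sim_variant_map <- function(cfg) {
  purrr::map_dfr(seq_len(cfg$n_chromosomes), function(chr) {
    pos <- sort(sample.int(cfg$chrom_length_bp, cfg$snps_per_chromosome))
    while (anyDuplicated(pos))
      pos <- sort(sample.int(cfg$chrom_length_bp, cfg$snps_per_chromosome))
    tibble(
      variant_id = sprintf("snp_%d_%d", chr, seq_along(pos)),
      chromosome = as.character(chr), position_bp = as.numeric(pos),
      allele_a = "A", allele_b = "B", cm = 0
    )
  })
}

#' Draw founder haplotype panels under the Balding-Nichols model
#'
#' Ancestral allele frequencies are uniform on [0.05, 0.95] per SNP (so MAF
#' filtering does not remove most sites by construction). Each population's
#' frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F) with F its `fst`; village
#' subgroups repeat the construction around the population frequencies with
#' `village_fst`. Founder haplotypes are drawn site-wise Bernoulli from the
#' panel frequencies.
#'
#' @param cfg a [sim_config()]. The config seed governs the draw.
#' @return A list with `variants` (map tibble), `ancestral` frequencies and
#'   per-panel founder matrices (`founders[[pop]][[subpop]]`,
#'   n_founders x n_snps).
#' @export
sim_founders <- function(cfg) {
  with_seed_or_not(cfg$seed, {
    variants <- sim_variant_map(cfg)
    m <- nrow(variants)
    p_anc <- runif(m, 0.05, 0.95)
    founders <- list()
    for (pop in cfg$populations) {
      f <- pop$fst
      p_pop <- rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      p_pop <- pmin(pmax(p_pop, 1e-4), 1 - 1e-4)
      panels <- list()
      if (is.null(pop$subpopulations)) {
        panels[[pop$name]] <- draw_panel(cfg$n_founders, p_pop)
      } else {
        for (v in names(pop$subpopulations)) {
          fv <- pop$village_fst
          p_v <- rbeta(m, p_pop * (1 - fv) / fv, (1 - p_pop) * (1 - fv) / fv)
          p_v <- pmin(pmax(p_v, 1e-4), 1 - 1e-4)
          panels[[v]] <- draw_panel(cfg$n_founders, p_v)
        }
      }
      founders[[pop$name]] <- list(panels = panels, freq = p_pop)
    }
    list(variants = variants, ancestral = p_anc, founders = founders)
  })
}

draw_panel <- function(n_founders, freq) {
  m <- length(freq)
  matrix(rbinom(n_founders * m, 1L, rep(freq, each = n_founders)), n_founders, m)
}

#' Simulate one population's phased haplotypes as founder mosaics
#'
#' Each sample haplotype copies a founder panel row, resampling the founder
#' index between adjacent SNPs with probability `1 - exp(-rate * gap_bp)`.
#' This produces linkage disequilibrium that decays with physical distance
#' at a rate set by `switch_rate_per_bp` and a background relatedness set
#' by the panel size.
#'
#' @param founders output of [sim_founders()].
#' @param cfg the [sim_config()].
#' @param population population name to simulate.
#' @param seed seed for this population's mosaic draw (NULL = session RNG).
#' @return A `haplotype_set` with `population`/`subpopulation` on the
#'   sample sheet.
#' @export
sim_population <- function(founders, cfg, population, seed = NULL) {
  pop <- purrr::detect(cfg$populations, ~ .x$name == population)
  if (is.null(pop)) stop_cs("unknown population: ", population)
  panels <- founders$founders[[population]]$panels
  sub_sizes <- pop$subpopulations %||% setNames(pop$n_samples, population)

  variants <- founders$variants
  with_seed_or_not(seed, {
    hap_rows <- list(); samp <- list(); k <- 1L
    for (v in names(sub_sizes)) {
      panel <- panels[[if (length(panels) == 1L) 1L else v]]
      for (i in seq_len(sub_sizes[[v]])) {
        sid <- sprintf("%s_%03d", population, k)
        h1 <- mosaic_haplotype(panel, variants, cfg$switch_rate_per_bp)
        h2 <- mosaic_haplotype(panel, variants, cfg$switch_rate_per_bp)
        hap_rows[[length(hap_rows) + 1L]] <- h1
        hap_rows[[length(hap_rows) + 1L]] <- h2
        samp[[k]] <- tibble(sample_id = sid, population = population,
                            subpopulation = if (length(panels) == 1L) NA_character_ else v)
        k <- k + 1L
      }
    }
    haplotype_set(do.call(rbind, hap_rows), variants, bind_rows(samp))
  })
}

# one mosaic haplotype across all chromosomes (independent per chromosome)
mosaic_haplotype <- function(panel, variants, rate) {
  nf <- nrow(panel)
  out <- integer(nrow(variants))
  for (chr in unique(variants$chromosome)) {
    vi <- which(variants$chromosome == chr)
    pos <- variants$position_bp[vi]
    mchr <- length(vi)
    p_switch <- 1 - exp(-rate * diff(pos))
    sw <- c(TRUE, runif(mchr - 1L) < p_switch)   # TRUE where a new founder starts
    block <- cumsum(sw)
    fid <- sample.int(nf, max(block), replace = TRUE)[block]
    out[vi] <- panel[cbind(fid, vi)]
  }
  out
}

#' Plant autozygous segments into a haplotype set
#'
#' Overwrites haplotype B with haplotype A inside non-overlapping segments
#' whose total length per sample equals `target` times the genome length
#' (segment lengths uniform on `[min_len_bp, max_len_bp]`, the last one
#' truncated to hit the total exactly; placement uniform with rejection of
#' overlaps). Planted segments are perfectly homozygous in the collapsed
#' genotypes; their coordinates are returned as truth.
#'
#' @param h a [haplotype_set()].
#' @param target expected F_ROH fraction in [0, 0.95).
#' @param min_len_bp,max_len_bp segment length bounds.
#' @param chrom_length_bp chromosome length (single value; all chromosomes
#'   are assumed equal length, as the simulator emits).
#' @param seed RNG seed (NULL = session RNG).
#' @return A list `(haplotypes, truth)` where truth is a tibble
#'   (`sample_id`, `chromosome`, `start_bp`, `end_bp`).
#' @export
plant_autozygosity <- function(h, target, min_len_bp = 1e6, max_len_bp = 8e6,
                               chrom_length_bp, seed = NULL) {
  if (target < 0 || target >= 0.95) stop_cs("target must lie in [0, 0.95)")
  chroms <- unique(h$variants$chromosome)
  genome_bp <- chrom_length_bp * length(chroms)
  if (target > 0 && min_len_bp > target * genome_bp)
    stop_cs("autozygosity target infeasible: one minimum-length segment exceeds the target total")
  if (min_len_bp > max_len_bp) stop_cs("min_len_bp > max_len_bp")
  truth <- list()
  if (target == 0) {
    return(list(
      haplotypes = h,
      truth = tibble(sample_id = character(), chromosome = character(),
                     start_bp = numeric(), end_bp = numeric())
    ))
  }
  hap <- h$haplotypes
  with_seed_or_not(seed, {
    for (i in seq_len(nrow(h$samples))) {
      need <- target * genome_bp
      placed <- stats::setNames(
        rep(list(matrix(numeric(0), 0, 2)), length(chroms)), chroms)
      total <- 0
      tries <- 0L
      while (total < need && tries < 2000L) {
        tries <- tries + 1L
        len <- runif(1, min_len_bp, max_len_bp)
        len <- min(len, need - total + 0)          # truncate the final segment
        if (need - total < min_len_bp) len <- need - total
        chr <- sample(chroms, 1)
        start <- runif(1, 1, max(1, chrom_length_bp - len))
        end <- start + len - 1
        prev <- placed[[chr]]
        if (nrow(prev) && any(start <= prev[, 2] & end >= prev[, 1])) next
        placed[[chr]] <- rbind(prev, c(start, end))
        total <- total + len
        vi <- which(h$variants$chromosome == chr &
                      h$variants$position_bp >= start &
                      h$variants$position_bp <= end)
        if (length(vi)) {
          rowA <- 2L * i - 1L
          hap[rowA + 1L, vi] <- hap[rowA, vi]
        }
        truth[[length(truth) + 1L]] <- tibble(
          sample_id = h$samples$sample_id[i], chromosome = chr,
          start_bp = start, end_bp = end)
      }
    }
  })
  h$haplotypes <- hap
  list(haplotypes = h,
       truth = if (length(truth)) bind_rows(truth) else
         tibble(sample_id = character(), chromosome = character(),
                start_bp = numeric(), end_bp = numeric()))
}

#' Plant a selective sweep into a haplotype set
#'
#' Emulates an incomplete sweep: at the marker nearest `core_position_bp`
#' the major allele is designated as the swept allele, a random
#' `carrier_fraction` of the haplotypes carrying it are chosen, and each
#' copies one donor carrier's alleles over a tract of exponential length
#' (mean `mean_tract_bp` on each side of the core, drawn per carrier and
#' side). Carriers thus share one long core haplotype whose homozygosity
#' decays smoothly with distance — the signal iHS/Rsb integrate — while
#' the core allele frequency itself is unchanged.
#'
#' @param h a [haplotype_set()].
#' @param chromosome chromosome of the core.
#' @param core_position_bp physical position of the core (snapped to the
#'   nearest marker).
#' @param carrier_fraction fraction of haplotypes homogenized, in (0,1].
#' @param mean_tract_bp mean one-sided tract length in bp.
#' @param seed RNG seed (NULL = session RNG).
#' @param core_variant optional explicit core marker id; an explicitly
#'   requested monomorphic core is an error (without it the core snaps to
#'   the nearest polymorphic marker).
#' @return A list `(haplotypes, truth)`; truth holds the snapped core
#'   marker (`chromosome`, `core_position_bp`, `core_variant`).
#' @export
plant_sweep <- function(h, chromosome, core_position_bp = NULL,
                        carrier_fraction = 0.8, mean_tract_bp = 1e6,
                        seed = NULL, core_variant = NULL) {
  vi <- which(h$variants$chromosome == chromosome)
  if (!length(vi)) stop_cs("no variants on chromosome ", chromosome)
  if (!is.null(core_variant)) {
    core <- vi[match(core_variant, h$variants$variant_id[vi])]
    if (is.na(core)) stop_cs("unknown core variant: ", core_variant)
    if (length(unique(h$haplotypes[, core])) < 2L)
      stop_cs("sweep core marker ", h$variants$variant_id[core], " is monomorphic")
  } else {
    # snap to the nearest marker that is polymorphic in this population
    freq <- colMeans(h$haplotypes[, vi, drop = FALSE])
    poly <- vi[freq > 0 & freq < 1]
    if (!length(poly))
      stop_cs("no polymorphic marker on chromosome ", chromosome,
              "; sweep core undefined")
    core <- poly[which.min(abs(h$variants$position_bp[poly] - core_position_bp))]
  }
  pos <- h$variants$position_bp
  with_seed_or_not(seed, {
    core_alleles <- h$haplotypes[, core]
    swept_allele <- as.integer(mean(core_alleles) >= 0.5)   # major at the core
    eligible <- which(core_alleles == swept_allele)
    n_car <- max(2L, round(carrier_fraction * length(eligible)))
    carriers <- sample(eligible, min(n_car, length(eligible)))
    donor <- carriers[1L]
    for (r in setdiff(carriers, donor)) {
      left <- rexp(1, 1 / mean_tract_bp)
      right <- rexp(1, 1 / mean_tract_bp)
      tract <- vi[pos[vi] >= pos[core] - left & pos[vi] <= pos[core] + right]
      tract <- union(tract, core)
      h$haplotypes[r, tract] <- h$haplotypes[donor, tract]
    }
  })
  list(
    haplotypes = h,
    truth = tibble(chromosome = as.character(chromosome),
                   core_position_bp = pos[core],
                   core_variant = h$variants$variant_id[core])
  )
}

#' Simulate a complete structured dataset with known truth
#'
#' Runs the whole generator: founder panels, per-population mosaics,
#' planted autozygosity per population target, planted sweeps. Everything
#' is derived deterministically from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list with `genotypes` (a [genotype_matrix()] over all
#'   samples), `haplotypes` (one `haplotype_set` per population, named) and
#'   `truth` (list: `ancestry`, `autozygous_segments`, `planted_sweeps`).
#' @export
sim_dataset <- function(cfg) {
  founders <- sim_founders(cfg)
  haps <- list(); auto_truth <- list(); sweep_truth <- list()
  for (k in seq_along(cfg$populations)) {
    pop <- cfg$populations[[k]]
    h <- sim_population(founders, cfg, pop$name, seed = cfg$seed + 1000L * k)
    pa <- plant_autozygosity(
      h, pop$autozygosity_target,
      min_len_bp = cfg$autozygosity_min_bp, max_len_bp = cfg$autozygosity_max_bp,
      chrom_length_bp = cfg$chrom_length_bp, seed = cfg$seed + 1000L * k + 1L)
    h <- pa$haplotypes
    auto_truth[[k]] <- pa$truth
    sweeps_here <- purrr::keep(cfg$sweeps, ~ .x$population == pop$name)
    for (j in seq_along(sweeps_here)) {
      s <- sweeps_here[[j]]
      ps <- plant_sweep(h, s$chromosome, s$core_position_bp,
                        s$carrier_fraction, s$mean_tract_bp,
                        seed = cfg$seed + 1000L * k + 10L + j)
      h <- ps$haplotypes
      sweep_truth[[length(sweep_truth) + 1L]] <-
        mutate(ps$truth, population = pop$name)
    }
    haps[[pop$name]] <- h
  }
  haps <- recode_major_ref(haps)
  genotypes <- merge_population_genotypes(haps)
  list(
    genotypes = genotypes,
    haplotypes = haps,
    truth = list(
      ancestry = genotypes$samples,
      autozygous_segments = bind_rows(auto_truth),
      planted_sweeps = if (length(sweep_truth)) bind_rows(sweep_truth) else
        tibble(chromosome = character(), core_position_bp = numeric(),
               core_variant = character(), population = character())
    )
  )
}

# orient each site so the reference allele (code 0) is the overall major
# allele, the standard chip/PLINK A2-style coding; allele letters follow
# the flip so collapsed genotypes stay consistent with the labels
recode_major_ref <- function(haps) {
  freq1 <- Reduce(`+`, purrr::map(haps, ~ colSums(.x$haplotypes))) /
    sum(purrr::map_int(haps, ~ nrow(.x$haplotypes)))
  flip <- freq1 > 0.5
  if (!any(flip)) return(haps)
  for (p in names(haps)) {
    haps[[p]]$haplotypes[, flip] <- 1L - haps[[p]]$haplotypes[, flip]
    v <- haps[[p]]$variants
    tmp <- v$allele_a[flip]
    v$allele_a[flip] <- v$allele_b[flip]
    v$allele_b[flip] <- tmp
    haps[[p]]$variants <- v
  }
  haps
}

merge_population_genotypes <- function(haps) {
  gms <- purrr::map(haps, collapse_haplotypes)
  calls <- do.call(rbind, purrr::map(gms, "calls"))
  samples <- bind_rows(purrr::map(gms, "samples"))
  genotype_matrix(calls, gms[[1]]$variants, samples)
}

#' Write a simulated dataset to disk
#'
#' Emits mutually consistent PED/MAP (unphased dosages), a phased VCF over
#' all samples, a sample sheet TSV and a machine-readable truth JSON.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named vector of the file paths.
#' @export
emit_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- sim_dataset(cfg)
  all_h <- merge_haplotype_sets(d$haplotypes)
  paths <- c(
    ped = file.path(out_dir, "genotypes.ped"),
    map = file.path(out_dir, "genotypes.map"),
    vcf = file.path(out_dir, "phased.vcf"),
    samples = file.path(out_dir, "samples.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_ped_map(d$genotypes, paths["ped"], paths["map"])
  write_phased_vcf(all_h, paths["vcf"])
  readr::write_tsv(d$genotypes$samples, paths["samples"])
  jsonlite::write_json(
    list(
      ancestry = d$truth$ancestry,
      autozygous_segments = d$truth$autozygous_segments,
      planted_sweeps = d$truth$planted_sweeps
    ),
    paths["truth"], digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Pool several haplotype sets over one variant map
#'
#' Stacks the samples of multiple [haplotype_set()]s sharing a variant
#' map — e.g. to pool comparator populations for an Rsb scan.
#'
#' @param haps list of `haplotype_set`s with identical variants.
#' @return A `haplotype_set`.
#' @export
merge_haplotype_sets <- function(haps) {
  ids <- purrr::map(haps, ~ .x$variants$variant_id)
  if (!all(purrr::map_lgl(ids, identical, ids[[1]])))
    stop_cs("haplotype sets must share one variant map")
  hap <- do.call(rbind, purrr::map(haps, "haplotypes"))
  samples <- bind_rows(purrr::map(haps, "samples"))
  haplotype_set(hap, haps[[1]]$variants, samples)
}
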