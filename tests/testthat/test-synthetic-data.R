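test_that("founder draws are deterministic and concentrate at small fst", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 1000,
                    chrom_length_bp = 30e6,
                    populations = list(sim_population_spec("a", 5, fst = 0.001)),
                    seed = 3)
  f1 <- sim_founders(cfg)
  f2 <- sim_founders(cfg)
  expect_identical(f1, f2)
  # fst -> 0: per-population frequencies hug the ancestral values
  p_pop <- colMeans(f1$founders$a$panels$a) # noisy (30 founders), so compare
  dev <- mean(abs(f1$founders$a$freq - f1$ancestral))
  expect_lt(dev, 0.02)
  expect_error(sim_config(populations = list(sim_population_spec("a", 5, fst = 0))),
               "fst")
})

test_that("realized FST tracks the Balding-Nichols parameter", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 5000,
                    chrom_length_bp = 100e6, switch_rate_per_bp = 1e-4,
                    populations = list(sim_population_spec("a", 50, fst = 0.2),
                                       sim_population_spec("b", 50, fst = 0.2)),
                    seed = 9)
  d <- sim_dataset(cfg)
  ga <- d$genotypes$calls[d$genotypes$samples$population == "a", ]
  gb <- d$genotypes$calls[d$genotypes$samples$population == "b", ]
  fst <- hudson_fst(colMeans(ga) / 2, colMeans(gb) / 2, 100, 100)
  expect_gt(fst, 0.1); expect_lt(fst, 0.3)
  # monotone in configured fst (fixed seeds)
  realized <- sapply(c(0.05, 0.15, 0.3), function(f) {
    cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 2000,
                      chrom_length_bp = 50e6,
                      populations = list(sim_population_spec("a", 30, fst = f),
                                         sim_population_spec("b", 30, fst = f)),
                      seed = 77)
    d <- sim_dataset(cfg)
    ga <- d$genotypes$calls[d$genotypes$samples$population == "a", ]
    gb <- d$genotypes$calls[d$genotypes$samples$population == "b", ]
    hudson_fst(colMeans(ga) / 2, colMeans(gb) / 2, 60, 60)
  })
  expect_true(all(diff(realized) > 0))
})

test_that("mosaic switching controls LD: limits and decay", {
  # switch rate ~ 0: every haplotype is a whole founder copy
  cfg0 <- sim_config(n_chromosomes = 1, snps_per_chromosome = 100,
                     chrom_length_bp = 1e7, switch_rate_per_bp = 0,
                     n_founders = 5,
                     populations = list(sim_population_spec("a", 10, fst = 0.1)),
                     seed = 12)
  f <- sim_founders(cfg0)
  h <- sim_population(f, cfg0, "a", seed = 1)
  panel <- f$founders$a$panels$a
  match_founder <- apply(h$haplotypes, 1, function(r)
    any(apply(panel, 1, function(p) all(p == r))))
  expect_true(all(match_founder))
  # large switch rate: near site-wise independence, r2 at 500 kb tiny
  cfg1 <- sim_config(n_chromosomes = 1, snps_per_chromosome = 500,
                     chrom_length_bp = 25e6, switch_rate_per_bp = 1e-3,
                     populations = list(sim_population_spec("a", 100, fst = 0.05)),
                     seed = 13)
  d <- sim_dataset(cfg1)
  pr <- pairwise_r2(d$genotypes, window_bp = 6e5, r2_floor = 0)
  far <- pr$r2[pr$distance_bp > 4e5]
  expect_gt(length(far), 500)
  expect_lt(mean(far), 0.05)
  # near-range mean r2 exceeds far-range at default switch rate
  cfg2 <- sim_config(n_chromosomes = 1, snps_per_chromosome = 600,
                     chrom_length_bp = 30e6,
                     populations = list(sim_population_spec("a", 60, fst = 0.05)),
                     seed = 14)
  d2 <- sim_dataset(cfg2)
  pr2 <- pairwise_r2(d2$genotypes, window_bp = 1e6, r2_floor = 0)
  expect_gt(mean(pr2$r2[pr2$distance_bp <= 5e4]),
            mean(pr2$r2[pr2$distance_bp > 5e5]))
})

test_that("planted autozygosity is homozygous, bounded and recorded", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 500,
                    chrom_length_bp = 50e6,
                    populations = list(sim_population_spec("a", 10, fst = 0.05)),
                    seed = 21)
  f <- sim_founders(cfg)
  h <- sim_population(f, cfg, "a", seed = 2)
  # target 0: identity, empty truth
  p0 <- plant_autozygosity(h, 0, chrom_length_bp = 50e6, seed = 3)
  expect_identical(p0$haplotypes$haplotypes, h$haplotypes)
  expect_equal(nrow(p0$truth), 0L)
  # planted segments are perfectly homozygous in the collapsed genotypes
  pa <- plant_autozygosity(h, 0.16, min_len_bp = 1e6, max_len_bp = 8e6,
                           chrom_length_bp = 50e6, seed = 4)
  g <- collapse_haplotypes(pa$haplotypes)
  for (r in sample.int(nrow(pa$truth), min(20, nrow(pa$truth)))) {
    tr <- pa$truth[r, ]
    i <- match(tr$sample_id, g$samples$sample_id)
    vi <- g$variants$chromosome == tr$chromosome &
      g$variants$position_bp >= tr$start_bp & g$variants$position_bp <= tr$end_bp
    expect_true(all(g$calls[i, vi] %in% c(0L, 2L)))
  }
  # total planted length per sample equals the target fraction exactly
  tot <- tapply(pa$truth$end_bp - pa$truth$start_bp + 1, pa$truth$sample_id, sum)
  expect_equal(as.numeric(tot) / 1e8, rep(0.16, 10), tolerance = 0.001)
  expect_true(all(pa$truth$end_bp <= 50e6))
  expect_error(plant_autozygosity(h, 0.96, chrom_length_bp = 50e6), "target")
  expect_error(plant_autozygosity(h, 0.001, min_len_bp = 5e6, max_len_bp = 8e6,
                                  chrom_length_bp = 50e6), "infeasible")
})

test_that("planted sweeps homogenize carriers and record the core", {
  cfg <- sim_config(n_chromosomes = 1, snps_per_chromosome = 300,
                    chrom_length_bp = 20e6,
                    populations = list(sim_population_spec("a", 20, fst = 0.05)),
                    seed = 31)
  f <- sim_founders(cfg)
  h <- sim_population(f, cfg, "a", seed = 5)
  ps <- plant_sweep(h, "1", 1e7, carrier_fraction = 1, mean_tract_bp = 1e9,
                    seed = 6)
  core_id <- ps$truth$core_variant
  expect_equal(
    ps$truth$core_position_bp,
    h$variants$position_bp[match(core_id, h$variants$variant_id)])
  # full-carrier, huge-tract sweep: EHH = 1 at every distance for the swept allele
  core_col <- match(core_id, ps$haplotypes$variants$variant_id)
  swept <- as.integer(mean(h$haplotypes[, core_col]) >= 0.5)
  e <- compute_ehh(ps$haplotypes, core_id, allele = swept, min_ehh = 0)
  expect_true(all(e$ehh == 1))
  # monomorphic explicit core errors
  hm <- h; hm$haplotypes[, 10] <- 0L
  expect_error(plant_sweep(hm, "1", core_variant = hm$variants$variant_id[10]),
               "monomorphic")
})

test_that("emitted datasets are deterministic and cross-format consistent", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 120,
                    chrom_length_bp = 8e6,
                    populations = list(sim_population_spec("p1", 8, fst = 0.1),
                                       sim_population_spec("p2", 7, fst = 0.1)),
                    seed = 41)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_dataset(cfg, d1)
  p2 <- emit_dataset(cfg, d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  g <- read_ped_map(p1["ped"], p1["map"])
  expect_equal(dim(g$calls), c(15L, 240L))
  truth <- jsonlite::read_json(p1["truth"], simplifyVector = TRUE)
  expect_equal(nrow(truth$ancestry), 15L)
})

test_that("planted autozygosity raises observed homozygosity monotonically", {
  hos <- sapply(c(0, 0.15, 0.3), function(tg) {
    cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 300,
                      chrom_length_bp = 30e6,
                      populations = list(
                        sim_population_spec("a", 12, fst = 0.05,
                                            autozygosity_target = tg)),
                      seed = 51)
    d <- sim_dataset(cfg)
    mean(observed_homozygosity(d$genotypes)$ho)
  })
  expect_true(all(diff(hos) > 0))
})
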