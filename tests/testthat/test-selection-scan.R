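test_that("EHH combinatorial formula matches brute-force pairwise identity", {
  # deterministic toy: 4 carriers split 2/2 at the next marker
  hap <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L),
               c(0L, 0L, 0L), c(0L, 1L, 0L))
  h <- toy_haplotypes(hap)
  e <- compute_ehh(h, "v1", allele = 1, min_ehh = 0)
  expect_equal(e$ehh[e$distance_bp == 0], 1)
  expect_equal(e$ehh[e$distance_bp == 1e4], 1 / 3)   # (1+1)/C(4,2)
  # identical carriers: EHH 1 everywhere
  hap1 <- rbind(matrix(1L, 4, 5), matrix(c(0L, 1L), 2, 5))
  h1 <- toy_haplotypes(hap1)
  e1 <- compute_ehh(h1, "v3", allele = 1, min_ehh = 0)
  expect_true(all(e1$ehh == 1))
  # randomized instances against the pairwise oracle, pooled and per-allele
  set.seed(55)
  for (i in 1:40) {
    nh <- 2 * sample(4:15, 1); m <- sample(10:40, 1)
    hap <- matrix(rbinom(nh * m, 1, runif(1, 0.3, 0.7)), nh, m)
    hh <- toy_haplotypes(hap)
    core <- sample(2:(m - 1), 1)
    for (al in c(0L, 1L)) {
      rows <- which(hap[, core] == al)
      if (length(rows) < 2) next
      e <- compute_ehh(hh, paste0("v", core), allele = al, min_ehh = 0,
                       max_gap_bp = Inf)
      for (r in seq_len(nrow(e))) {
        tgt <- match(e$variant_id[r], hh$variants$variant_id)
        expect_equal(e$ehh[r], ehh_pairwise_oracle(hap, rows, core, tgt),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("EHH is non-increasing outward and truncates correctly", {
  set.seed(56)
  hap <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  h <- toy_haplotypes(hap)
  e <- compute_ehh(h, "v15", allele = hap[1, 15], min_ehh = 0, max_gap_bp = Inf)
  up <- e$ehh[e$distance_bp >= 0]
  dn <- rev(e$ehh[e$distance_bp <= 0])
  expect_true(all(diff(up) <= 1e-12))
  expect_true(all(diff(dn) <= 1e-12))
  # truncation at min_ehh: no emitted value below the threshold
  et <- compute_ehh(h, "v15", allele = hap[1, 15], min_ehh = 0.05)
  expect_true(all(et$ehh >= 0.05))
  expect_error(compute_ehh(toy_haplotypes(matrix(c(1L, 0L, 0L, 0L), 4, 3)),
                           "v1", allele = 1), "carriers")
})

test_that("iHH integration follows the trapezoid rule", {
  curve <- tibble::tibble(variant_id = c("a", "b"), position_bp = c(0, 1e4),
                          distance_bp = c(0, 1e4), ehh = c(1, 1))
  expect_equal(integrate_ehh(curve), 1e4)
  curve2 <- tibble::tibble(distance_bp = c(0, 1e4), ehh = c(1, 1 / 3))
  expect_equal(integrate_ehh(curve2), (1 + 1 / 3) / 2 * 1e4)
  # no flanking markers: degenerate zero
  expect_equal(integrate_ehh(tibble::tibble(distance_bp = 0, ehh = 1)), 0)
})

test_that("iHS is antisymmetric under allele relabeling and matches toy areas", {
  # two-marker toy: carriers of allele 1 split 2/2 at the flank (EHH 1/3),
  # carriers of allele 0 identical (EHH 1), flank 10 kb away
  hap <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L),
               c(0L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L))
  h <- toy_haplotypes(hap, positions = c(1e4, 2e4))
  s <- ihs_scan(h, min_maf = 0, min_ehh = 0)
  # iHH_ref = 1 * 10k (identical), iHH_alt = (1 + 1/3)/2 * 10k
  expect_equal(s$ihs[1], log(1e4 / ((1 + 1 / 3) / 2 * 1e4)), tolerance = 1e-9)
  hflip <- toy_haplotypes(1L - hap, positions = c(1e4, 2e4))
  sflip <- ihs_scan(hflip, min_maf = 0, min_ehh = 0)
  expect_equal(sflip$ihs[1], -s$ihs[1], tolerance = 1e-12)
  # identical EHH profiles for both alleles: iHS = 0
  hap0 <- rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L), c(0L, 1L, 0L))
  s0 <- ihs_scan(toy_haplotypes(hap0), min_maf = 0, min_ehh = 0)
  expect_equal(s0$ihs[1], 0)
})

test_that("Rsb is antisymmetric under population swap and zero on self", {
  set.seed(57)
  hap1 <- matrix(rbinom(16 * 20, 1, 0.5), 16, 20)
  hap2 <- matrix(rbinom(12 * 20, 1, 0.5), 12, 20)
  h1 <- toy_haplotypes(hap1); h2 <- toy_haplotypes(hap2)
  r12 <- rsb_scan(h1, h2, min_ehh = 0)
  r21 <- rsb_scan(h2, h1, min_ehh = 0)
  expect_equal(r12$rsb, -r21$rsb, tolerance = 1e-12)
  rself <- rsb_scan(h1, h1, min_ehh = 0)
  expect_true(all(abs(rself$rsb) < 1e-12, na.rm = TRUE))
})

test_that("window geometry follows the 15-SNP step-7 rule with flagged tail", {
  sites <- tibble::tibble(chromosome = "1",
                          position_bp = seq(1e5, by = 1e5, length.out = 31),
                          ihs = rnorm(31))
  w <- window_statistics(sites, "ihs")
  expect_equal(nrow(w), 4L)                 # offsets 0, 7, 14 + 10-site tail
  expect_equal(w$n_snp, c(15L, 15L, 15L, 10L))
  expect_equal(w$tail, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(w$usable, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(w$start_bp[2], sites$position_bp[8])
  # constant values give constant means; a linear ramp gives centered means
  sites$ihs <- rep(2.5, 31)
  expect_true(all(window_statistics(sites, "ihs")$mean_stat == 2.5))
  sites$ihs <- seq_len(31)
  wr <- window_statistics(sites, "ihs")
  expect_equal(wr$mean_stat[1:3], c(8, 15, 22))
  # windows with < 8 informative sites are flagged unusable
  sites$ihs[1:10] <- NA
  wf <- window_statistics(sites, "ihs")
  expect_false(wf$usable[1])
})

test_that("fractional-rank p-values match the rank definition with ties", {
  w <- tibble::tibble(chromosome = "1", start_bp = seq_len(100) * 1e5,
                      end_bp = seq_len(100) * 1e5 + 5e4, n_snp = 15L,
                      n_informative = 15L, mean_stat = seq_len(100) / 10,
                      usable = TRUE, tail = FALSE)
  wr <- rank_pvalues(w, "right")
  expect_equal(wr$p_value[which.max(wr$mean_stat)], 0.01)
  expect_equal(wr$neg_log10_p[which.max(wr$mean_stat)], 2)
  # two-tailed median of 101 distinct values has p near 1
  w101 <- dplyr::bind_rows(w, w[1, ]); w101$mean_stat <- seq_len(101)
  wt <- rank_pvalues(w101, "two")
  expect_gte(wt$p_value[51], 1 - 2 / 101)
  # all equal: every p = 1
  w$mean_stat <- 1
  expect_true(all(rank_pvalues(w, "right")$p_value == 1))
  expect_true(all(rank_pvalues(w, "two")$p_value == 1))
})

test_that("candidate regions need two chained significant windows", {
  base <- tibble::tibble(chromosome = "1",
                         start_bp = c(1e6, 1.5e6, 4e6),
                         end_bp = c(1.4e6, 1.9e6, 4.4e6),
                         n_snp = 15L, n_informative = 15L,
                         mean_stat = c(5, 4, 1), usable = TRUE, tail = FALSE,
                         p_value = c(0.001, 0.005, 0.5),
                         neg_log10_p = c(3, 2.3, 0.3))
  # two significant windows 100 kb apart, peak first
  reg <- call_candidate_regions(base, max_gap_bp = 1e5)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_bp, 1e6)
  expect_equal(reg$end_bp, 1.4e6)
  expect_equal(reg$n_windows, 2L)
  # isolated single significant window: nothing
  iso <- base; iso$neg_log10_p <- c(3, 0.5, 0.4)
  expect_equal(nrow(call_candidate_regions(iso)), 0L)
  # 150 kb gap exceeds the 100 kb rule
  far <- base; far$start_bp[2] <- 1.55e6; far$end_bp[2] <- 1.95e6
  expect_equal(nrow(call_candidate_regions(far, max_gap_bp = 1e5)), 0L)
})

test_that("planted sweeps elevate windowed iHS over the swept tract", {
  # the swept allele is the core-region major allele; with major-reference
  # coding raw iHS over the tract is pushed positive, so windows covering
  # the core should rank in the upper tail of the signed window means
  res <- t(sapply(1:6, function(seed) {
    cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 800,
                      chrom_length_bp = 55e6,
                      populations = list(sim_population_spec("a", 50, fst = 0.08)),
                      sweeps = list(sim_sweep_spec("a", "1", 27e6, 0.8, 1e6)),
                      seed = 900 + seed)
    d <- sim_dataset(cfg)
    s <- ihs_scan(d$haplotypes$a)
    core_id <- d$truth$planted_sweeps$core_variant[1]
    i <- match(core_id, s$variant_id)
    w <- rank_pvalues(window_statistics(s, "ihs"), "two")
    covers <- w$usable & w$chromosome == "1" &
      w$start_bp <= s$position_bp[i] & w$end_bp >= s$position_bp[i]
    q90 <- quantile(w$mean_stat[w$usable], 0.9)
    near <- s$chromosome == "1" & abs(s$position_bp - s$position_bp[i]) < 7e5
    c(window_top = any(covers) && max(w$mean_stat[covers]) >= q90,
      tract_positive = mean(s$ihs[near], na.rm = TRUE) > mean(s$ihs, na.rm = TRUE))
  }))
  expect_gte(sum(res[, "window_top"]), 5)
  expect_gte(sum(res[, "tract_positive"]), 5)
})
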