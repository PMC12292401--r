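test_that("call rates follow the strict-threshold exclusion rules", {
  g <- toy_genotypes(rbind(c(0L, 1L, NA, 2L),
                           c(0L, 1L, 1L, 2L)))
  cr <- call_rates(g)
  expect_equal(cr$samples$call_rate, c(0.75, 1))
  expect_equal(cr$variants$call_rate, c(1, 1, 0.5, 1))

  # a sample at exactly the threshold is retained (strict "<")
  calls <- matrix(0L, 3, 100)
  calls[1, 1:6] <- NA          # 0.94
  calls[2, 1:5] <- NA          # 0.95 exactly
  g <- toy_genotypes(calls)
  res <- suppressWarnings(apply_qc(g, "diversity", variant_call_rate = 0,
                                   maf_threshold = -1))
  expect_equal(res$report$excluded_samples_call_rate$ids, "s1")

  expect_error(call_rates(toy_genotypes(matrix(integer(0), 0, 0))))
})

test_that("exact HWE test matches full enumeration and handles edge tables", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(50, 0, 0), 1)
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  # all genotype tables with n <= 12 against the choose()-based oracle
  for (n in c(2, 5, 9, 12)) {
    tabs <- expand.grid(aa = 0:n, ab = 0:n)
    tabs <- tabs[tabs$aa + tabs$ab <= n, ]
    for (r in seq_len(nrow(tabs))) {
      aa <- tabs$aa[r]; ab <- tabs$ab[r]; bb <- n - aa - ab
      expect_equal(hwe_exact_test(aa, ab, bb), hwe_oracle(aa, ab, bb),
                   tolerance = 1e-9)
    }
  }
})

test_that("HWE null rejection rate is calibrated at alpha = 0.05", {
  set.seed(7)
  n <- 100; m <- 2000
  p <- runif(m, 0.1, 0.9)
  g1 <- rbinom(m, n, p^2)
  g2 <- rbinom(m, n, 2 * p * (1 - p) / (1 - p^2))  # not exact HW sampling
  # draw true HWE genotype tables: multinomial per SNP
  tabs <- sapply(p, function(pp) rmultinom(1, n, c(pp^2, 2 * pp * (1 - pp), (1 - pp)^2)))
  pv <- hwe_exact_test(tabs[1, ], tabs[2, ], tabs[3, ])
  rej <- mean(pv < 0.05)
  se <- sqrt(0.05 * 0.95 / m)
  expect_lte(rej, 0.05 + 2 * se)   # discreteness makes the test conservative
})

test_that("IBS sharing is symmetric and matches the allele-sharing formula", {
  g <- toy_genotypes(rbind(c(0L, 1L), c(1L, 2L), c(0L, 1L), c(2L, 0L)))
  expect_equal(ibs_proportion(g, "s1", "s2"), 0.5)
  expect_equal(ibs_proportion(g, "s2", "s1"), 0.5)
  expect_equal(ibs_proportion(g, "s1", "s3"), 1)
  expect_equal(ibs_proportion(g, 1, 4), 0.25)
  g2 <- toy_genotypes(rbind(c(0L, NA), c(NA, 2L)))
  expect_error(ibs_proportion(g2, 1, 2), "no non-missing")
})

test_that("minor allele frequency uses non-missing denominators and the <= rule", {
  g <- toy_genotypes(rbind(matrix(0L, 40, 1), matrix(1L, 20, 1), matrix(2L, 40, 1)))
  expect_equal(minor_allele_freq(g)$maf, 0.5)
  g2 <- toy_genotypes(matrix(c(rep(0L, 99), 1L), 100, 1))
  expect_equal(minor_allele_freq(g2)$maf, 0.005)
  # exactly 0.05 is excluded by the cascade
  set.seed(11)
  filler <- matrix(sample(0:2, 50 * 10, TRUE, c(.25, .5, .25)), 50, 10)
  calls <- cbind(filler, matrix(c(rep(1L, 5), rep(0L, 45))))  # maf 0.05 exactly
  res <- suppressWarnings(apply_qc(toy_genotypes(calls), "selection"))
  expect_equal(res$report$excluded_variants_maf$ids, "v11")
})

test_that("greedy LD pruning keeps the first of correlated pairs", {
  set.seed(1)
  x <- sample(0:2, 30, TRUE)
  y <- sample(0:2, 30, TRUE)
  g <- toy_genotypes(cbind(x, x, y), positions = c(1e5, 2e5, 3e5))
  expect_equal(ld_prune(g, 0.5, 1e6), c("v1", "v3"))
  # chain 1-2, 2-3 correlated but 1-3 not: greedy keeps {1, 3}
  z1 <- c(rep(0L, 15), rep(2L, 15))
  z2 <- z1; z2[c(1, 2, 16, 17)] <- 2L - z2[c(1, 2, 16, 17)]
  z3 <- z2; z3[c(5, 6, 20, 21)] <- 2L - z3[c(5, 6, 20, 21)]
  g2 <- toy_genotypes(cbind(z1, z2, z3), positions = c(1e5, 2e5, 3e5))
  r12 <- cor(z1, z2)^2; r23 <- cor(z2, z3)^2; r13 <- cor(z1, z3)^2
  expect_true(r12 > 0.5 && r23 > 0.5 && r13 < 0.5)
  expect_equal(ld_prune(g2, 0.5, 1e6), c("v1", "v3"))
  # uncorrelated variants are all retained
  set.seed(2)
  gu <- toy_genotypes(matrix(sample(0:2, 40 * 6, TRUE), 40, 6))
  expect_equal(length(ld_prune(gu, 0.99, 1e6)), 6L)
})

test_that("QC cascade attributes exclusions to the first violated criterion", {
  set.seed(3)
  m <- 40; n <- 20
  base <- matrix(sample(0:2, n * m, TRUE, c(.25, .5, .25)), n, m)
  g <- toy_genotypes(base)
  # clean matrix: nothing excluded (keep thresholds permissive for maf)
  res <- suppressWarnings(apply_qc(g, "diversity", maf_threshold = 0.0,
                                   hwe_p = 1e-12))
  expect_equal(sum(tidy(res$report)$n_excluded), 0L)

  # planted violations in distinct variants: 2 with missing calls,
  # 1 extreme HWE violation, 3 low-MAF; one duplicate sample pair
  calls <- base
  calls[1, 1] <- NA; calls[2, 2] <- NA
  calls[, 3] <- rep(c(0L, 2L), n / 2)          # het deficit -> HWE
  calls[, 4] <- c(1L, rep(0L, n - 1))          # maf 1/40 <= .05
  calls[, 5] <- c(1L, rep(0L, n - 1))
  calls[, 6] <- c(1L, rep(0L, n - 1))
  calls[n, ] <- calls[n - 1, ]                 # IBS duplicate
  g2 <- toy_genotypes(calls)
  res2 <- suppressWarnings(apply_qc(g2, "selection", hwe_p = 1e-3))
  rep2 <- res2$report
  expect_equal(rep2$excluded_samples_ibs$n, 1L)
  expect_equal(rep2$excluded_variants_call_rate$n, 2L)
  expect_equal(rep2$excluded_variants_hwe$n, 1L)
  expect_equal(rep2$excluded_variants_maf$n, 3L)
  expect_equal(rep2$excluded_variants_ld$n, 0L)   # selection profile: no pruning

  # multi-population input triggers the stratification warning
  gw <- toy_genotypes(base, populations = rep(c("a", "b"), 10))
  expect_warning(apply_qc(gw, "diversity", maf_threshold = 0, hwe_p = 1e-12),
                 "stratification")
})

test_that("QC output is invariant to sample order", {
  set.seed(4)
  calls <- matrix(sample(0:2, 30 * 25, TRUE), 30, 25)
  calls[, 1] <- c(1L, rep(0L, 29))
  g <- toy_genotypes(calls)
  perm <- sample(30)
  gp <- subset_genotypes(g, samples = perm)
  r1 <- suppressWarnings(apply_qc(g, "selection"))
  r2 <- suppressWarnings(apply_qc(gp, "selection"))
  expect_setequal(r1$genotypes$samples$sample_id, r2$genotypes$samples$sample_id)
  expect_equal(r1$genotypes$variants, r2$genotypes$variants)
})
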