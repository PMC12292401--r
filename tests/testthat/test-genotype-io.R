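test_that("PED/MAP round trip preserves genotypes, alleles and missingness", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")

  # single-genotype encoding and missing-code rule
  writeLines("1\tv1\t0\t100", map)
  writeLines(c("fam1 s1 0 0 0 -9 A A",
               "fam1 s2 0 0 0 -9 A G",
               "fam1 s3 0 0 0 -9 A 0"), ped)
  g <- read_ped_map(ped, map)
  expect_equal(unname(g$calls[, 1]), c(0L, 1L, NA))
  expect_equal(g$variants$allele_a, "A")   # first observed
  expect_equal(g$variants$allele_b, "G")
  expect_equal(g$samples$population, rep("fam1", 3))

  # random matrix round trip (canonical orientation: read of a written
  # file is a fixed point, so write/read twice and compare)
  set.seed(42)
  calls <- matrix(sample(c(0:2, NA), 10 * 50, TRUE, c(.3, .3, .3, .1)), 10, 50)
  g0 <- toy_genotypes(calls, chromosome = rep(c("1", "2"), each = 25),
                      positions = rep(seq(1e5, by = 1e5, length.out = 25), 2))
  write_ped_map(g0, ped, map)
  g1 <- read_ped_map(ped, map)
  write_ped_map(g1, ped, map)
  g2 <- read_ped_map(ped, map)
  expect_equal(g2$calls, g1$calls)
  expect_equal(g2$variants, g1$variants)
  expect_equal(g2$samples, g1$samples)
  # encoding conservation on the first pass: per-variant allele counts
  b0 <- colSums(g0$calls, na.rm = TRUE)
  b1 <- colSums(g1$calls, na.rm = TRUE)
  nobs <- colSums(!is.na(g0$calls))
  expect_true(all(b1 == b0 | b1 == 2 * nobs - b0))  # up to orientation
  expect_equal(is.na(g1$calls), is.na(g0$calls), ignore_attr = TRUE)
})

test_that("PED parser rejects malformed input and drops non-autosomal variants", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\tv1\t0\t100", "1\tv2\t0\t200"), map)
  writeLines("fam s1 0 0 0 -9 A A", ped)    # 1 genotype for 2 variants
  expect_error(read_ped_map(ped, map), "line 1")

  writeLines(c("1\tv1\t0\t100", "1\tv1\t0\t200"), map)
  writeLines("fam s1 0 0 0 -9 A A G G", ped)
  expect_error(read_ped_map(ped, map), "duplicate")

  writeLines(c("1\tv1\t0\t100", "1\tv2\t0\t200"), map)
  writeLines(c("fam s1 0 0 0 -9 A A G G",
               "fam s2 0 0 0 -9 C A G G",
               "fam s3 0 0 0 -9 T A G G"), ped)
  expect_error(read_ped_map(ped, map), "v1")

  # sex-chromosome and unmapped variants dropped with a message
  writeLines(c("1\tv1\t0\t100", "X\tv2\t0\t200", "0\tv3\t0\t300"), map)
  writeLines("fam s1 0 0 0 -9 A A G G T T", ped)
  expect_message(g <- read_ped_map(ped, map), "dropped 2")
  expect_equal(g$variants$variant_id, "v1")

  # empty sample list still yields a valid MAP and empty PED body
  g0 <- toy_genotypes(matrix(integer(0), 0, 2))
  p2 <- withr::local_tempfile(fileext = ".ped")
  m2 <- withr::local_tempfile(fileext = ".map")
  write_ped_map(g0, p2, m2)
  expect_equal(length(readLines(p2)), 0L)
  expect_equal(nrow(utils::read.table(m2)), 2L)
})

test_that("phased VCF reading transcribes haplotypes and enforces phasing", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", sep = "\t"))
  writeLines(c(hdr, "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"), vcf)
  h <- read_phased_vcf(vcf, "1")
  expect_equal(unname(h$haplotypes[, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(h$sample_of_row, c("s1", "s1", "s2", "s2"))

  writeLines(c(hdr, "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1"), vcf)
  expect_error(read_phased_vcf(vcf, "1"), "phased")
  writeLines(c(hdr, "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t.|.\t1|1"), vcf)
  expect_error(read_phased_vcf(vcf, "1"), "phased")
})

test_that("haplotype pair sums equal the jointly emitted genotype matrix", {
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 60,
                    chrom_length_bp = 5e6,
                    populations = list(sim_population_spec("p1", 6, fst = 0.1),
                                       sim_population_spec("p2", 5, fst = 0.1)),
                    seed = 11)
  out <- withr::local_tempdir()
  paths <- emit_dataset(cfg, out)
  g <- read_ped_map(paths["ped"], paths["map"])
  h <- read_phased_vcf(paths["vcf"])
  gh <- collapse_haplotypes(h)
  # same variants, and identical allele-b counts up to PED orientation
  expect_equal(gh$variants$variant_id, g$variants$variant_id)
  nobs <- 2L * nrow(g$samples)
  bg <- colSums(g$calls)
  bh <- colSums(gh$calls)
  expect_true(all(bg == bh | bg == nobs - bh))
  # per-cell consistency after orienting to the VCF coding
  flip <- !is.na(g$variants$allele_b) & g$variants$allele_b != gh$variants$allele_b
  calls <- g$calls
  calls[, flip] <- 2L - calls[, flip]
  expect_equal(unname(calls), unname(gh$calls))
})

test_that("BED interval output is 0-based half-open", {
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed_intervals(tibble::tibble(chromosome = "1", start_bp = 1000,
                                     end_bp = 2000, name = "x"), bed)
  expect_equal(readLines(bed), "1\t999\t2000\tx")
})
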