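#' Per-sample and per-variant genotyping call rates
#'
#' @param g a [genotype_matrix()].
#' @return A list of two tibbles: `samples` (`sample_id`, `call_rate`) and
#'   `variants` (`variant_id`, `call_rate`), rates in [0,1].
#' @export
call_rates <- function(g) {
  if (nrow(g$calls) == 0L || ncol(g$calls) == 0L)
    stop_cs("call_rates needs at least one sample and one variant")
  obs <- !is.na(g$calls)
  list(
    samples = tibble(sample_id = g$samples$sample_id,
                     call_rate = unname(rowMeans(obs))),
    variants = tibble(variant_id = g$variants$variant_id,
                      call_rate = unname(colMeans(obs)))
  )
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Full conditional enumeration: given the observed allele counts, every
#' compatible heterozygote count is enumerated, each table's conditional
#' probability computed, and the p-value is the sum of probabilities no
#' larger than the observed table's (two-sided exact test in the
#' Fisher sense). Vectorized over genotype-count triples.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom-a, het, hom-b).
#' @return Numeric vector of p-values in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (length(n_ab) != length(n_aa) || length(n_bb) != length(n_aa))
    stop_cs("genotype count vectors must have equal length")
  mapply(function(aa, ab, bb) {
    n <- aa + ab + bb
    if (n < 1) stop_cs("HWE test needs at least one genotyped sample")
    na <- 2L * aa + ab              # copies of allele a
    hets <- seq.int(na %% 2L, min(na, 2L * n - na), by = 2L)
    # log conditional probability of each heterozygote count
    h <- hets
    lp <- lfactorial(n) - lfactorial((na - h) / 2) - lfactorial(h) -
      lfactorial((2 * n - na - h) / 2) + h * log(2)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    obs <- pr[match(ab, hets)]
    sum(pr[pr <= obs * (1 + 1e-12)])
  }, n_aa, n_ab, n_bb)
}

#' Per-variant minor allele frequency
#'
#' @param g a [genotype_matrix()].
#' @return Tibble `variant_id`, `maf` (in [0, 0.5]); errors if a variant
#'   has no non-missing calls.
#' @export
minor_allele_freq <- function(g) {
  nobs <- colSums(!is.na(g$calls))
  if (any(nobs == 0L))
    stop_cs("variant(s) with no non-missing calls: ",
            paste(head(g$variants$variant_id[nobs == 0], 3), collapse = ", "))
  f <- colSums(g$calls, na.rm = TRUE) / (2 * nobs)
  tibble(variant_id = g$variants$variant_id, maf = unname(pmin(f, 1 - f)))
}

#' Identity-by-state proportion between two samples
#'
#' Mean allele sharing over jointly non-missing variants:
#' `(2 - |g_i - g_j|) / 2`.
#'
#' @param g a [genotype_matrix()].
#' @param sample_i,sample_j sample ids or row indices.
#' @return A proportion in [0, 1].
#' @export
ibs_proportion <- function(g, sample_i, sample_j) {
  i <- resolve_index(sample_i, g$samples$sample_id)
  j <- resolve_index(sample_j, g$samples$sample_id)
  gi <- g$calls[i, ]; gj <- g$calls[j, ]
  ok <- !is.na(gi) & !is.na(gj)
  if (!any(ok)) stop_cs("samples share no non-missing variants")
  mean((2 - abs(gi[ok] - gj[ok])) / 2)
}

#' All pairwise IBS proportions
#'
#' @param g a [genotype_matrix()].
#' @return Tibble `sample_i`, `sample_j`, `ibs` for all unordered pairs.
#' @export
ibs_pairs <- function(g) {
  n <- nrow(g$samples)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble(
    sample_i = g$samples$sample_id[pairs[, 1]],
    sample_j = g$samples$sample_id[pairs[, 2]],
    ibs = purrr::map2_dbl(pairs[, 1], pairs[, 2], ~ ibs_proportion(g, .x, .y))
  )
}

#' Greedy LD pruning
#'
#' Left-to-right scan per chromosome: each retained variant removes later
#' variants within `window_bp` whose genotypic r-squared with it exceeds
#' `r2_threshold` (greedy keep-first by map order).
#'
#' @param g a [genotype_matrix()].
#' @param r2_threshold prune pairs with r² strictly above this.
#' @param window_bp maximum pair distance considered.
#' @return Character vector of retained variant ids, in map order.
#' @export
ld_prune <- function(g, r2_threshold = 0.5, window_bp = 1e6) {
  keep <- logical(nrow(g$variants))
  for (chr in unique(g$variants$chromosome)) {
    vi <- which(g$variants$chromosome == chr)
    pos <- g$variants$position_bp[vi]
    alive <- rep(TRUE, length(vi))
    for (a in seq_along(vi)) {
      if (!alive[a]) next
      keep[vi[a]] <- TRUE
      b <- which(alive & seq_along(vi) > a & pos - pos[a] <= window_bp)
      if (!length(b)) next
      r2 <- vapply(b, function(bb) dosage_r2(g$calls[, vi[a]], g$calls[, vi[bb]]), numeric(1))
      alive[b[!is.na(r2) & r2 > r2_threshold]] <- FALSE
    }
  }
  g$variants$variant_id[keep]
}

# squared Pearson correlation of two dosage vectors over shared calls;
# NA when either is monomorphic on the shared set
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' QC cascade with per-criterion exclusion accounting
#'
#' Applies the standard SNP-array QC cascade in a fixed order — sample call
#' rate, sample IBS duplicates, variant call rate, exact HWE, MAF
#' (profile-dependent), LD pruning (profile-dependent) — and attributes
#' each exclusion to the first criterion that removed it.
#'
#' Profiles: `"structure"` applies MAF and LD pruning; `"selection"` and
#' `"diversity"` apply MAF but no pruning.
#'
#' Thresholds (defaults follow common chip practice): samples with call
#' rate strictly below `sample_call_rate` are dropped; of an IBS pair
#' above `ibs_threshold` the lower-call-rate sample is dropped (ties:
#' lexicographically larger id); variants with call rate strictly below
#' `variant_call_rate` (default 1: any missingness), exact HWE p strictly
#' below `hwe_p`, or MAF less than or equal to `maf_threshold` are
#' dropped; pruning removes pairs with r² strictly above `ld_r2`.
#'
#' HWE is tested on the dataset as given; if it contains several
#' populations a stratification warning is emitted (population structure
#' inflates HWE rejections).
#'
#' @param g a [genotype_matrix()].
#' @param profile one of `"structure"`, `"selection"`, `"diversity"`.
#' @param sample_call_rate,ibs_threshold,variant_call_rate,hwe_p,maf_threshold,ld_r2,ld_window_bp
#'   cascade thresholds.
#' @return A list of class `qc_result`: `genotypes` (filtered matrix) and
#'   `report` (a `qc_report` list of counts, ids and thresholds).
#' @export
apply_qc <- function(g, profile = c("structure", "selection", "diversity"),
                     sample_call_rate = 0.95, ibs_threshold = 0.95,
                     variant_call_rate = 1.0, hwe_p = 1e-6,
                     maf_threshold = 0.05, ld_r2 = 0.5, ld_window_bp = 1e6) {
  profile <- match.arg(profile)
  if (length(unique(g$samples$population)) > 1L)
    warn(paste0("apply_qc: HWE is tested on a multi-population dataset; ",
                "stratification can inflate HWE rejections"))

  cr <- call_rates(g)
  drop_samples_cr <- cr$samples$sample_id[cr$samples$call_rate < sample_call_rate]
  g1 <- subset_genotypes(g, samples = setdiff(g$samples$sample_id, drop_samples_cr))

  ibs <- ibs_pairs(g1)
  high <- filter(ibs, .data$ibs > ibs_threshold)
  drop_samples_ibs <- character(0)
  if (nrow(high)) {
    rates <- setNames(call_rates(g1)$samples$call_rate, g1$samples$sample_id)
    for (r in seq_len(nrow(high))) {
      a <- high$sample_i[r]; b <- high$sample_j[r]
      if (a %in% drop_samples_ibs || b %in% drop_samples_ibs) next
      drop <- if (rates[a] < rates[b]) a
        else if (rates[b] < rates[a]) b
        else max(a, b)                       # tie: lexicographically larger id
      drop_samples_ibs <- c(drop_samples_ibs, drop)
    }
  }
  g2 <- subset_genotypes(g1, samples = setdiff(g1$samples$sample_id, drop_samples_ibs))

  crv <- call_rates(g2)$variants
  drop_var_cr <- crv$variant_id[crv$call_rate < variant_call_rate]
  g3 <- subset_genotypes(g2, variants = setdiff(g2$variants$variant_id, drop_var_cr))

  counts <- genotype_counts(g3)
  hwe <- hwe_exact_test(counts$n_aa, counts$n_ab, counts$n_bb)
  drop_var_hwe <- g3$variants$variant_id[hwe < hwe_p]
  g4 <- subset_genotypes(g3, variants = setdiff(g3$variants$variant_id, drop_var_hwe))

  drop_var_maf <- character(0)
  if (profile %in% c("structure", "selection", "diversity")) {
    maf <- minor_allele_freq(g4)
    drop_var_maf <- maf$variant_id[maf$maf <= maf_threshold]
    g4 <- subset_genotypes(g4, variants = setdiff(g4$variants$variant_id, drop_var_maf))
  }

  drop_var_ld <- character(0)
  if (profile == "structure") {
    retained <- ld_prune(g4, r2_threshold = ld_r2, window_bp = ld_window_bp)
    drop_var_ld <- setdiff(g4$variants$variant_id, retained)
    g4 <- subset_genotypes(g4, variants = retained)
  }

  if (ncol(g4$calls) == 0L || nrow(g4$calls) == 0L)
    stop_cs("QC removed every sample or variant; nothing left to analyse")

  report <- structure(list(
    excluded_samples_call_rate = list(n = length(drop_samples_cr), ids = drop_samples_cr),
    excluded_samples_ibs = list(n = length(drop_samples_ibs), ids = drop_samples_ibs,
                                pairs = high[, c("sample_i", "sample_j")]),
    excluded_variants_call_rate = list(n = length(drop_var_cr), ids = drop_var_cr),
    excluded_variants_hwe = list(n = length(drop_var_hwe), ids = drop_var_hwe),
    excluded_variants_maf = list(n = length(drop_var_maf), ids = drop_var_maf),
    excluded_variants_ld = list(n = length(drop_var_ld), ids = drop_var_ld),
    thresholds = list(profile = profile, sample_call_rate = sample_call_rate,
                      ibs_threshold = ibs_threshold,
                      variant_call_rate = variant_call_rate, hwe_p = hwe_p,
                      maf_threshold = maf_threshold, ld_r2 = ld_r2,
                      ld_window_bp = ld_window_bp)
  ), class = "qc_report")

  structure(list(genotypes = g4, report = report), class = "qc_result")
}

# per-variant genotype counts (hom allele_a, het, hom allele_b)
genotype_counts <- function(g) {
  tibble(
    variant_id = g$variants$variant_id,
    n_aa = colSums(g$calls == 0L, na.rm = TRUE),
    n_ab = colSums(g$calls == 1L, na.rm = TRUE),
    n_bb = colSums(g$calls == 2L, na.rm = TRUE)
  )
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("QC report (profile: ", x$thresholds$profile, ")\n", sep = "")
  cat("  samples excluded, call rate < ", x$thresholds$sample_call_rate, ": ",
      x$excluded_samples_call_rate$n, "\n", sep = "")
  cat("  samples excluded, IBS > ", x$thresholds$ibs_threshold, ": ",
      x$excluded_samples_ibs$n, "\n", sep = "")
  cat("  variants excluded, call rate: ", x$excluded_variants_call_rate$n, "\n", sep = "")
  cat("  variants excluded, HWE p < ", format(x$thresholds$hwe_p), ": ",
      x$excluded_variants_hwe$n, "\n", sep = "")
  cat("  variants excluded, MAF <= ", x$thresholds$maf_threshold, ": ",
      x$excluded_variants_maf$n, "\n", sep = "")
  cat("  variants excluded, LD r2 > ", x$thresholds$ld_r2, ": ",
      x$excluded_variants_ld$n, "\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.qc_result <- function(x, ...) {
  print(x$report)
  print(x$genotypes)
  invisible(x)
}

#' Tidy a QC report into one row per criterion
#'
#' @param x a `qc_report`.
#' @param ... unused.
#' @return Tibble `criterion`, `axis`, `n_excluded`.
#' @export
tidy.qc_report <- function(x, ...) {
  tibble(
    criterion = c("sample_call_rate", "sample_ibs", "variant_call_rate",
                  "hwe", "maf", "ld"),
    axis = c("sample", "sample", "variant", "variant", "variant", "variant"),
    n_excluded = c(x$excluded_samples_call_rate$n, x$excluded_samples_ibs$n,
                   x$excluded_variants_call_rate$n, x$excluded_variants_hwe$n,
                   x$excluded_variants_maf$n, x$excluded_variants_ld$n)
  )
}
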