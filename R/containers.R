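#' Genotype matrix container
#'
#' Bundles a dense samples x variants matrix of alt-allele dosages with the
#' variant map and sample sheet. Dosages count copies of `allele_b`
#' (0, 1, 2); `NA` marks a missing call. Variants are kept sorted by
#' (chromosome, position).
#'
#' @param calls integer matrix, samples x variants, values in `{0,1,2,NA}`.
#' @param variants tibble with columns `variant_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b` (and optionally `cm`).
#' @param samples tibble with columns `sample_id`, `population` and
#'   optionally `subpopulation`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  if (!"subpopulation" %in% names(samples)) samples$subpopulation <- NA_character_
  if (!"cm" %in% names(variants)) variants$cm <- 0
  g <- structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(g)
}

validate_genotype_matrix <- function(g) {
  calls <- g$calls
  if (nrow(calls) != nrow(g$samples))
    stop_cs("call matrix has ", nrow(calls), " rows but ", nrow(g$samples), " samples")
  if (ncol(calls) != nrow(g$variants))
    stop_cs("call matrix has ", ncol(calls), " columns but ", nrow(g$variants), " variants")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop_cs("genotype calls must be 0, 1, 2 or NA")
  if (anyDuplicated(g$variants$variant_id))
    stop_cs("duplicate variant ids: ",
            paste(head(g$variants$variant_id[duplicated(g$variants$variant_id)], 3), collapse = ", "))
  if (anyDuplicated(g$samples$sample_id))
    stop_cs("duplicate sample ids")
  ord <- order(chrom_rank(g$variants$chromosome), g$variants$position_bp)
  if (!identical(ord, seq_len(nrow(g$variants)))) {
    g$variants <- g$variants[ord, ]
    g$calls <- g$calls[, ord, drop = FALSE]
  }
  by_chr <- split(g$variants$position_bp, g$variants$chromosome)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1))))
    stop_cs("variant positions must be strictly increasing within a chromosome")
  dimnames(g$calls) <- list(g$samples$sample_id, g$variants$variant_id)
  g
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$samples), " samples x ", nrow(x$variants),
      " variants on ", length(unique(x$variants$chromosome)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat("  populations: ", paste(unique(x$samples$population), collapse = ", "),
      "; missing calls: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param g a [genotype_matrix()].
#' @param samples logical/integer/character index into samples.
#' @param variants logical/integer/character index into variants.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  si <- resolve_index(samples, g$samples$sample_id)
  vi <- resolve_index(variants, g$variants$variant_id)
  genotype_matrix(g$calls[si, vi, drop = FALSE], g$variants[vi, ], g$samples[si, ])
}

resolve_index <- function(idx, ids) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    m <- match(idx, ids)
    if (anyNA(m)) stop_cs("unknown ids: ", paste(head(idx[is.na(m)], 3), collapse = ", "))
    return(m)
  }
  if (is.logical(idx)) return(which(idx))
  idx
}

#' Phased haplotype container
#'
#' Holds phased alleles as a (2 * samples) x variants 0/1 matrix, rows in
#' consecutive pairs per sample (sample1 hap A, sample1 hap B, sample2 hap
#' A, ...). May span several chromosomes; haplotype statistics operate per
#' chromosome.
#'
#' @param haplotypes integer 0/1 matrix with `2 * length(samples)` rows.
#' @param variants variant tibble as in [genotype_matrix()].
#' @param samples character vector of sample ids, or a sample tibble.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(haplotypes, variants, samples) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (is.data.frame(samples)) samples <- as_tibble(samples) else
    samples <- tibble(sample_id = as.character(samples))
  if (!"population" %in% names(samples)) samples$population <- NA_character_
  variants <- as_tibble(variants)
  if (nrow(haplotypes) != 2L * nrow(samples))
    stop_cs("haplotype matrix must have 2 rows per sample")
  if (ncol(haplotypes) != nrow(variants))
    stop_cs("haplotype matrix has ", ncol(haplotypes), " columns but ",
            nrow(variants), " variants")
  vals <- haplotypes[!is.na(haplotypes)]
  if (anyNA(haplotypes) || (length(vals) && any(vals != 0L & vals != 1L)))
    stop_cs("haplotype alleles must be 0 or 1 with no missing values")
  ord <- order(chrom_rank(variants$chromosome), variants$position_bp)
  variants <- variants[ord, ]
  haplotypes <- haplotypes[, ord, drop = FALSE]
  structure(
    list(
      haplotypes = haplotypes, variants = variants, samples = samples,
      sample_of_row = rep(samples$sample_id, each = 2L)
    ),
    class = "haplotype_set"
  )
}

#' @exportS3Method base::print
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", nrow(x$samples), " samples (",
      nrow(x$haplotypes), " haplotypes) x ", nrow(x$variants), " variants on ",
      length(unique(x$variants$chromosome)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Collapse phased haplotypes to unphased genotype dosages
#'
#' Sums each sample's haplotype pair, giving the alt-allele dosage matrix
#' that [genotype_matrix()] holds. Inverse check of the phased/unphased
#' consistency invariant.
#'
#' @param h a [haplotype_set()].
#' @return A `genotype_matrix` over the same samples and variants.
#' @export
collapse_haplotypes <- function(h) {
  idx <- seq_len(nrow(h$samples))
  calls <- h$haplotypes[2L * idx - 1L, , drop = FALSE] +
    h$haplotypes[2L * idx, , drop = FALSE]
  variants <- h$variants
  if (!"allele_a" %in% names(variants)) variants$allele_a <- "A"
  if (!"allele_b" %in% names(variants)) variants$allele_b <- "B"
  genotype_matrix(calls, variants, h$samples)
}

#' Subset a haplotype set by chromosome, samples and/or variants
#'
#' @param h a [haplotype_set()].
#' @param chromosome chromosome label to keep (NULL keeps all).
#' @param samples sample ids or index to keep (NULL keeps all).
#' @param variants variant ids or index to keep (NULL keeps all).
#' @return A `haplotype_set`.
#' @export
subset_haplotypes <- function(h, chromosome = NULL, samples = NULL,
                              variants = NULL) {
  vi <- resolve_index(variants, h$variants$variant_id)
  if (!is.null(chromosome))
    vi <- vi[h$variants$chromosome[vi] %in% chromosome]
  si <- resolve_index(samples, h$samples$sample_id)
  rows <- as.vector(rbind(2L * si - 1L, 2L * si))
  haplotype_set(h$haplotypes[rows, vi, drop = FALSE], h$variants[vi, ], h$samples[si, ])
}

#' Drop low-frequency variants from a haplotype set
#'
#' Restricts the phased data to variants whose minor allele frequency
#' (over the set's haplotypes) reaches `min_maf` — the dataset the
#' haplotype-based selection scans are meant to run on, where EHH
#' extension traverses only the retained markers.
#'
#' @param h a [haplotype_set()].
#' @param min_maf minimum minor allele frequency.
#' @return A `haplotype_set`.
#' @export
filter_haplotypes_maf <- function(h, min_maf = 0.05) {
  f <- colMeans(h$haplotypes)
  subset_haplotypes(h, variants = which(pmin(f, 1 - f) >= min_maf))
}
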