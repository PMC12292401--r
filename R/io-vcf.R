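#' Read phased haplotypes from a VCF
#'
#' Reads biallelic, fully phased GT records (pipe-separated, e.g. `0|1`)
#' into a [haplotype_set()]. REF maps to allele 0 and ALT to allele 1.
#' Haplotype-based statistics need complete phased data, so any unphased
#' (`/`) or missing genotype is an error naming the offending record.
#'
#' @param vcf_path path to a VCF 4.x file (plain text or gzip).
#' @param chromosome chromosome label to extract; `NULL` reads all records.
#' @param populations optional tibble (`sample_id`, `population`) attached
#'   to the sample sheet.
#' @return A `haplotype_set`.
#' @export
read_phased_vcf <- function(vcf_path, chromosome = NULL, populations = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- if (is.null(chromosome)) seq_len(nrow(fix)) else which(fix$CHROM %in% chromosome)
  if (!length(keep)) stop_cs("no VCF records on chromosome ", chromosome)
  fix <- fix[keep, , drop = FALSE]
  gt <- v@gt[keep, -1, drop = FALSE]
  sample_ids <- colnames(v@gt)[-1]

  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop_cs("multi-allelic record not supported: ", fix$ID[which(multi)[1]],
            " at ", fix$CHROM[which(multi)[1]], ":", fix$POS[which(multi)[1]])

  # GT is the first colon-separated field
  gt_only <- matrix(sub(":.*$", "", gt), nrow(gt), ncol(gt))
  ok <- matrix(grepl("^[01]\\|[01]$", gt_only), nrow(gt_only), ncol(gt_only))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, , drop = TRUE]
    stop_cs("genotype '", gt_only[bad[1], bad[2]], "' for sample ",
            sample_ids[bad[2]], " at record ", fix$CHROM[bad[1]], ":",
            fix$POS[bad[1]],
            " is not fully phased (expected allele1|allele2, no missing)")
  }

  m <- nrow(fix); n <- length(sample_ids)
  hap <- matrix(0L, 2L * n, m)
  hap1 <- substr(gt_only, 1L, 1L) == "1"
  hap2 <- substr(gt_only, 3L, 3L) == "1"
  hap[seq(1L, 2L * n, by = 2L), ] <- t(matrix(as.integer(hap1), m, n))
  hap[seq(2L, 2L * n, by = 2L), ] <- t(matrix(as.integer(hap2), m, n))

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  variants <- tibble(
    variant_id = ids, chromosome = fix$CHROM,
    position_bp = as.numeric(fix$POS), allele_a = fix$REF, allele_b = fix$ALT,
    cm = 0
  )
  samples <- tibble(sample_id = sample_ids)
  if (!is.null(populations))
    samples <- left_join(samples, as_tibble(populations), by = "sample_id")
  haplotype_set(hap, variants, samples)
}

#' Write a haplotype set as a phased VCF
#'
#' Emits a minimal VCF 4.2 with GT-only FORMAT and pipe-separated phased
#' genotypes, readable by [read_phased_vcf()].
#'
#' @param h a [haplotype_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(h, path) {
  n <- nrow(h$samples); m <- nrow(h$variants)
  idx <- seq_len(n)
  h1 <- h$haplotypes[2L * idx - 1L, , drop = FALSE]
  h2 <- h$haplotypes[2L * idx, , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), m, n)   # m x n
  v <- h$variants
  ref <- ifelse(is.na(v$allele_a), "A", v$allele_a)
  alt <- ifelse(is.na(v$allele_b), "B", v$allele_b)
  body <- paste(
    v$chromosome, format(v$position_bp, scientific = FALSE, trim = TRUE),
    v$variant_id, ref, alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=capriscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", h$samples$sample_id), collapse = "\t")
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Converts 1-based inclusive internal coordinates to the 0-based
#' half-open BED convention.
#'
#' @param intervals tibble with `chromosome`, `start_bp`, `end_bp` and
#'   optionally a `name` column.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed_intervals <- function(intervals, path) {
  name <- intervals[["name"]] %||% rep(".", nrow(intervals))
  bed <- data.frame(
    intervals$chromosome,
    format(intervals$start_bp - 1, scientific = FALSE, trim = TRUE),
    format(intervals$end_bp, scientific = FALSE, trim = TRUE),
    name
  )
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
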