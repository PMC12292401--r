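#' Read PLINK text PED/MAP genotypes
#'
#' Parses the classic whitespace-separated PED/MAP pair into a
#' [genotype_matrix()]. The MAP supplies the marker map (chromosome, id,
#' genetic position, bp); the PED supplies six pedigree columns followed by
#' two allele columns per marker, with `0` as the missing-allele code. The
#' PED family-ID column populates the population label. Variants on
#' non-autosomal or unmapped chromosomes (labels that are not positive
#' integers, or position 0) are dropped with a message.
#'
#' Allele orientation: for each variant, `allele_a` is the first allele
#' observed while scanning the PED and `allele_b` the second; dosages count
#' `allele_b` copies. Squared/absolute statistics downstream are invariant
#' to this arbitrary orientation.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param subpop_path optional TSV with columns `sample_id`,
#'   `subpopulation` providing within-population labels.
#' @return A `genotype_matrix`.
#' @export
read_ped_map <- function(ped_path, map_path, subpop_path = NULL) {
  map <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(map) != 4L)
    stop_cs("MAP file must have 4 columns (chrom, id, cM, bp), found ", ncol(map))
  names(map) <- c("chromosome", "variant_id", "cm", "position_bp")
  map$position_bp <- as.numeric(map$position_bp)
  map$cm <- as.numeric(map$cm)
  if (anyDuplicated(map$variant_id))
    stop_cs("duplicate variant ids in MAP: ",
            paste(head(unique(map$variant_id[duplicated(map$variant_id)]), 3), collapse = ", "))

  keep <- is_autosome_label(map$chromosome) & map$position_bp >= 1
  if (any(!keep))
    inform(paste0("read_ped_map: dropped ", sum(!keep),
                  " unmapped/non-autosomal variant(s)"))
  m_all <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  expected <- 6L + 2L * m_all

  fam <- character(n); sid <- character(n)
  alle1 <- matrix("0", n, m_all); alle2 <- matrix("0", n, m_all)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != expected)
      stop_cs("PED line ", i, " has ", length(tok), " fields, expected ", expected,
              " for ", m_all, " MAP variants")
    fam[i] <- tok[1]; sid[i] <- tok[2]
    gt <- tok[-(1:6)]
    alle1[i, ] <- gt[c(TRUE, FALSE)]
    alle2[i, ] <- gt[c(FALSE, TRUE)]
  }

  map <- map[keep, , drop = FALSE]
  alle1 <- alle1[, keep, drop = FALSE]
  alle2 <- alle2[, keep, drop = FALSE]
  m <- nrow(map)

  calls <- matrix(NA_integer_, n, m)
  allele_a <- character(m); allele_b <- character(m)
  for (j in seq_len(m)) {
    a <- c(rbind(alle1[, j], alle2[, j]))     # PED scan order within sample
    obs <- a[a != "0"]
    lev <- unique(obs)
    if (length(lev) > 2L)
      stop_cs("variant ", map$variant_id[j], " has ", length(lev),
              " distinct alleles; only biallelic sites are supported")
    allele_a[j] <- if (length(lev) >= 1L) lev[1] else NA_character_
    allele_b[j] <- if (length(lev) == 2L) lev[2] else NA_character_
    miss <- alle1[, j] == "0" | alle2[, j] == "0"
    if (length(lev)) {
      d <- (alle1[, j] == allele_b[j]) + (alle2[, j] == allele_b[j])
      if (is.na(allele_b[j])) d <- rep(0L, n)
      calls[, j] <- ifelse(miss, NA_integer_, as.integer(d))
    }
  }

  samples <- tibble(sample_id = sid, population = fam)
  if (!is.null(subpop_path)) {
    sp <- readr::read_tsv(subpop_path, show_col_types = FALSE)
    samples <- left_join(samples, sp[, c("sample_id", "subpopulation")], by = "sample_id")
  }
  variants <- tibble(
    variant_id = map$variant_id, chromosome = map$chromosome,
    position_bp = map$position_bp, allele_a = allele_a, allele_b = allele_b,
    cm = map$cm
  )
  genotype_matrix(calls, variants, samples)
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' Inverse of [read_ped_map()]: a round trip reproduces the matrix exactly
#' (allele labels, orientation and missingness included). Missing calls are
#' written as `0 0`.
#'
#' @param g a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  v <- g$variants
  map <- data.frame(v$chromosome, v$variant_id, v$cm %||% 0, format(v$position_bp, scientific = FALSE, trim = TRUE))
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  n <- nrow(g$samples); m <- nrow(v)
  a <- ifelse(is.na(v$allele_a), "0", v$allele_a)
  b <- ifelse(is.na(v$allele_b), "0", v$allele_b)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    gi <- g$calls[i, ]
    a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, b, a))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, b, a))
    # heterozygotes are written allele_a first so first-observed order is stable
    a1[!is.na(gi) & gi == 1L] <- a[!is.na(gi) & gi == 1L]
    a2[!is.na(gi) & gi == 1L] <- b[!is.na(gi) & gi == 1L]
    row <- c(g$samples$population[i], g$samples$sample_id[i], "0", "0", "0", "-9",
             as.vector(rbind(a1, a2)))
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}
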