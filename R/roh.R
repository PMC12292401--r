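#' Parameters for consecutive-SNP ROH detection
#'
#' Defaults follow standard chip practice for livestock: at least 15 SNPs
#' per run, at most 2 opposing (heterozygous) genotypes, no missing calls,
#' at most 1 Mb between consecutive SNPs in a run, minimum run length 1 kb.
#'
#' @param min_snp minimum SNPs per run.
#' @param max_opp maximum heterozygous genotypes allowed in a run.
#' @param max_miss maximum missing genotypes allowed in a run.
#' @param max_gap_bp maximum distance between consecutive SNPs in a run.
#' @param min_length_bp minimum run span (first to last SNP, inclusive).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snp = 15, max_opp = 2, max_miss = 0,
                       max_gap_bp = 1e6, min_length_bp = 1000) {
  stopifnot(min_snp >= 1, max_opp >= 0, max_miss >= 0,
            max_gap_bp >= 0, min_length_bp >= 0)
  structure(list(min_snp = as.integer(min_snp), max_opp = as.integer(max_opp),
                 max_miss = as.integer(max_miss), max_gap_bp = max_gap_bp,
                 min_length_bp = min_length_bp),
            class = "roh_params")
}

#' Detect runs of homozygosity by the consecutive-SNP method
#'
#' Scans each sample's chromosomes for maximal runs of consecutive SNPs in
#' which the heterozygote count stays within `max_opp`, the missing count
#' within `max_miss`, and every adjacent inter-SNP gap within
#' `max_gap_bp`. Runs are extended greedily left to right (budgets are
#' per-run), trimmed to homozygous non-missing endpoints, and kept when
#' they reach `min_snp` SNPs and `min_length_bp` bp. Segment coordinates
#' are first-SNP to last-SNP inclusive; `length_bp = end - start + 1`.
#' Runs are non-overlapping per sample.
#'
#' @param g a [genotype_matrix()].
#' @param params a [roh_params()].
#' @param samples subset of sample ids (default: all).
#' @return Tibble `sample_id`, `population`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_snp`, `length_bp`.
#' @export
detect_roh <- function(g, params = roh_params(), samples = NULL) {
  si <- resolve_index(samples, g$samples$sample_id)
  out <- list()
  for (chr in unique(g$variants$chromosome)) {
    vi <- which(g$variants$chromosome == chr)
    pos <- g$variants$position_bp[vi]
    if (is.unsorted(pos, strictly = TRUE))
      stop_cs("variant map is not sorted on chromosome ", chr)
    gaps <- diff(pos)
    for (i in si) {
      calls <- g$calls[i, vi]
      segs <- roh_scan_one(calls, pos, gaps, params)
      if (nrow(segs)) {
        segs$sample_id <- g$samples$sample_id[i]
        segs$population <- g$samples$population[i]
        segs$chromosome <- chr
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  cols <- c("sample_id", "population", "chromosome", "start_bp", "end_bp",
            "n_snp", "length_bp")
  if (!length(out))
    return(as_tibble(setNames(
      list(character(), character(), character(), numeric(), numeric(),
           integer(), numeric()), cols)))
  bind_rows(out)[, cols]
}

# greedy left-to-right maximal-run scan on one sample x chromosome.
# state per SNP: 0 homozygous, 1 heterozygous, 2 missing
roh_scan_one <- function(calls, pos, gaps, p) {
  state <- ifelse(is.na(calls), 2L, ifelse(calls == 1L, 1L, 0L))
  m <- length(state)
  segs <- list()
  s <- 1L
  while (s <= m) {
    # candidate runs start at a homozygous SNP
    while (s <= m && state[s] != 0L) s <- s + 1L
    if (s > m) break
    het <- 0L; mis <- 0L; e <- s
    j <- s + 1L
    while (j <= m) {
      if (gaps[j - 1L] > p$max_gap_bp) break
      ht <- het + (state[j] == 1L)
      ms <- mis + (state[j] == 2L)
      if (ht > p$max_opp || ms > p$max_miss) break
      het <- ht; mis <- ms
      j <- j + 1L
    }
    e <- j - 1L
    while (e > s && state[e] != 0L) e <- e - 1L   # trim to homozygous endpoint
    n_snp <- e - s + 1L
    len <- pos[e] - pos[s] + 1
    if (n_snp >= p$min_snp && len >= p$min_length_bp)
      segs[[length(segs) + 1L]] <- c(pos[s], pos[e], n_snp, len)
    s <- max(e + 1L, s + 1L)
  }
  if (!length(segs))
    return(tibble(start_bp = numeric(), end_bp = numeric(),
                  n_snp = integer(), length_bp = numeric()))
  mat <- do.call(rbind, segs)
  tibble(start_bp = mat[, 1], end_bp = mat[, 2],
         n_snp = as.integer(mat[, 3]), length_bp = mat[, 4])
}

#' Genomic inbreeding from ROH (F_ROH)
#'
#' Sum of each individual's ROH lengths divided by the total autosome
#' length (genome-wide), plus the chromosome-wise analogue.
#'
#' @param segments segment tibble from [detect_roh()] (any subset of
#'   samples).
#' @param autosome_lengths tibble `chromosome`, `length_bp`.
#' @param sample_ids samples to report (default: those present in
#'   `segments`); supply the full sample list to include zero-ROH samples.
#' @return A list of two tibbles: `genome` (`sample_id`, `froh`) and
#'   `by_chromosome` (`sample_id`, `chromosome`, `froh`).
#' @export
froh <- function(segments, autosome_lengths, sample_ids = NULL) {
  if (any(autosome_lengths$length_bp <= 0))
    stop_cs("autosome lengths must be positive")
  chrom_len <- setNames(autosome_lengths$length_bp, autosome_lengths$chromosome)
  seg_len <- chrom_len[segments$chromosome]
  if (anyNA(seg_len))
    stop_cs("segment on chromosome absent from autosome_lengths")
  if (any(segments$end_bp > seg_len))
    stop_cs("segment extends beyond its chromosome length")
  total_bp <- sum(autosome_lengths$length_bp)
  ids <- sample_ids %||% unique(segments$sample_id)
  gen <- segments %>%
    group_by(.data$sample_id) %>%
    summarise(froh = sum(.data$length_bp) / total_bp, .groups = "drop")
  genome <- tibble(sample_id = ids) %>%
    left_join(gen, by = "sample_id") %>%
    mutate(froh = tidyr::replace_na(.data$froh, 0))
  by_chr <- tidyr::expand_grid(sample_id = ids,
                               chromosome = autosome_lengths$chromosome) %>%
    left_join(
      segments %>%
        group_by(.data$sample_id, .data$chromosome) %>%
        summarise(roh_bp = sum(.data$length_bp), .groups = "drop"),
      by = c("sample_id", "chromosome")) %>%
    left_join(autosome_lengths, by = "chromosome") %>%
    mutate(froh = tidyr::replace_na(.data$roh_bp, 0) / .data$length_bp) %>%
    select("sample_id", "chromosome", "froh")
  list(genome = genome, by_chromosome = by_chr)
}

#' Classify ROH segments into size classes
#'
#' Standard five livestock size classes with left-open/right-closed
#' boundaries at 2, 4, 8 and 16 Mb (a segment of exactly 2 Mb falls in the
#' first class).
#'
#' @param segments segment tibble from [detect_roh()].
#' @return Tibble `size_class`, `n`, `fraction` (fractions are zero, with
#'   an `empty` attribute, when no segment exists).
#' @export
roh_size_classes <- function(segments) {
  breaks <- c(0, 2e6, 4e6, 8e6, 16e6, Inf)
  labs <- c("0-2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb", ">16 Mb")
  cls <- cut(segments$length_bp, breaks, labels = labs, right = TRUE)
  n <- as.integer(table(cls))
  out <- tibble(size_class = labs, n = n,
                fraction = if (sum(n)) n / sum(n) else rep(0, 5))
  attr(out, "empty") <- sum(n) == 0L
  out
}

#' Call ROH islands from population ROH prevalence
#'
#' Computes, per SNP, the fraction of samples whose ROH cover that SNP's
#' position; maximal runs of consecutive SNPs at or above
#' `threshold_fraction` become islands spanning the first to last
#' qualifying SNP (inclusive). Runs are never merged across a prevalence
#' dip.
#'
#' @param segments ROH tibble from [detect_roh()] across all samples.
#' @param g the [genotype_matrix()] providing the SNP map and sample count.
#' @param threshold_fraction prevalence threshold in (0, 1].
#' @return Tibble `chromosome`, `start_bp`, `end_bp`, `n_snp`,
#'   `peak_prevalence`.
#' @export
roh_islands <- function(segments, g, threshold_fraction = 0.5) {
  if (!(threshold_fraction > 0 && threshold_fraction <= 1))
    stop_cs("threshold_fraction must lie in (0, 1]")
  n_samples <- nrow(g$samples)
  out <- list()
  for (chr in unique(g$variants$chromosome)) {
    vi <- which(g$variants$chromosome == chr)
    pos <- g$variants$position_bp[vi]
    cov <- integer(length(vi))
    segs <- segments[segments$chromosome == chr, ]
    for (sid in unique(segs$sample_id)) {
      ss <- segs[segs$sample_id == sid, ]
      covered <- rep(FALSE, length(vi))
      for (r in seq_len(nrow(ss)))
        covered <- covered | (pos >= ss$start_bp[r] & pos <= ss$end_bp[r])
      cov <- cov + covered
    }
    prev <- cov / n_samples
    qual <- prev >= threshold_fraction
    if (!any(qual)) next
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      i1 <- starts[b]; i2 <- ends[b]
      out[[length(out) + 1L]] <- tibble(
        chromosome = chr, start_bp = pos[i1], end_bp = pos[i2],
        n_snp = i2 - i1 + 1L, peak_prevalence = max(prev[i1:i2]))
    }
  }
  if (!length(out))
    return(tibble(chromosome = character(), start_bp = numeric(),
                  end_bp = numeric(), n_snp = integer(),
                  peak_prevalence = numeric()))
  bind_rows(out)
}

#' Per-SNP ROH prevalence
#'
#' @inheritParams roh_islands
#' @return Tibble `chromosome`, `position_bp`, `prevalence`.
#' @export
roh_prevalence <- function(segments, g) {
  out <- purrr::map_dfr(unique(g$variants$chromosome), function(chr) {
    vi <- which(g$variants$chromosome == chr)
    pos <- g$variants$position_bp[vi]
    cov <- integer(length(vi))
    segs <- segments[segments$chromosome == chr, ]
    for (sid in unique(segs$sample_id)) {
      ss <- segs[segs$sample_id == sid, ]
      covered <- rep(FALSE, length(vi))
      for (r in seq_len(nrow(ss)))
        covered <- covered | (pos >= ss$start_bp[r] & pos <= ss$end_bp[r])
      cov <- cov + covered
    }
    tibble(chromosome = chr, position_bp = pos, prevalence = cov / nrow(g$samples))
  })
  out
}
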