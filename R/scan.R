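#' Extended haplotype homozygosity around a core marker
#'
#' EHH for the haplotypes carrying `allele` at the core (or pooled over
#' all haplotypes for the site-specific variant, EHHS): moving outward
#' from the core, carriers are partitioned by their allele string from the
#' core to each marker, and `EHH(m) = sum_g C(n_g, 2) / C(n, 2)`. The
#' curve equals 1 at the core, is non-increasing outward, and is truncated
#' at the first marker where it falls below `min_ehh` or at an inter-marker
#' gap above `max_gap_bp`.
#'
#' @param h a [haplotype_set()].
#' @param core_variant variant id of the core marker.
#' @param allele 0, 1, or `"pooled"` for EHHS.
#' @param min_ehh truncation threshold on EHH.
#' @param max_gap_bp maximum tolerated inter-marker gap.
#' @return Tibble `variant_id`, `position_bp`, `distance_bp` (signed
#'   offset from the core), `ehh`.
#' @export
compute_ehh <- function(h, core_variant, allele = 1, min_ehh = 0.05,
                        max_gap_bp = 1e6) {
  core <- match(core_variant, h$variants$variant_id)
  if (is.na(core)) stop_cs("unknown core variant: ", core_variant)
  chr <- h$variants$chromosome[core]
  vi <- which(h$variants$chromosome == chr)
  hap <- h$haplotypes[, vi, drop = FALSE]
  core_l <- match(core, vi)
  pos <- h$variants$position_bp[vi]
  rows <- if (identical(allele, "pooled")) seq_len(nrow(hap)) else
    which(hap[, core_l] == allele)
  if (length(rows) < 2L)
    stop_cs("EHH undefined: fewer than 2 carriers of allele ", allele,
            " at ", core_variant)
  cv <- ehh_curve_cpp(hap, as.integer(rows - 1L), as.integer(core_l - 1L),
                      pos, min_ehh, max_gap_bp)
  idx <- cv$col + 1L
  tibble(
    variant_id = h$variants$variant_id[vi[idx]],
    position_bp = pos[idx],
    distance_bp = pos[idx] - pos[core_l],
    ehh = cv$ehh
  )
}

#' Integrate an EHH curve over physical distance
#'
#' Trapezoid rule on each side of the core (the row with
#' `distance_bp == 0`), areas summed; bp-scaled. A curve with no flanking
#' markers integrates to 0.
#'
#' @param site_ehh tibble from [compute_ehh()].
#' @return iHH in bp (a single non-negative number).
#' @export
integrate_ehh <- function(site_ehh) {
  d <- site_ehh$distance_bp
  e <- site_ehh$ehh
  if (!any(d == 0)) stop_cs("curve must contain the core row (distance 0)")
  area <- 0
  for (side in c(-1, 1)) {
    sel <- sign(d) == side
    ord <- order(abs(d[sel]))
    dd <- c(0, abs(d[sel])[ord])
    ee <- c(e[d == 0][1], e[sel][ord])
    if (length(dd) > 1L)
      area <- area + sum((head(ee, -1) + tail(ee, -1)) / 2 * diff(dd))
  }
  area
}

#' Genome-wide iHS scan (unstandardized by default)
#'
#' For each marker, integrates EHH separately for the reference
#' (`allele_a`, coded 0) and alternative (`allele_b`, coded 1) alleles and
#' takes `iHS = ln(iHH_ref / iHH_alt)`. Sites with minor allele frequency
#' below `min_maf`, fewer than 2 carriers of either allele, or a zero
#' integral on either side are returned as `NA` (skipped sites). The raw
#' log-ratio is what sliding windows average; the conventional
#' frequency-bin z-standardization is available with
#' `standardize = TRUE` but is off by default.
#'
#' @param h a [haplotype_set()] for one population.
#' @param min_maf minimum minor allele frequency for a usable core.
#' @param min_ehh,max_gap_bp truncation rules, see [compute_ehh()].
#' @param standardize z-score the log-ratios within derived-frequency bins.
#' @param n_bins frequency bins used when `standardize = TRUE`.
#' @return Tibble `variant_id`, `chromosome`, `position_bp`, `freq_alt`,
#'   `ihh_ref`, `ihh_alt`, `ihs` (plus `ihs_raw` when standardizing).
#' @export
ihs_scan <- function(h, min_maf = 0.05, min_ehh = 0.05, max_gap_bp = 1e6,
                     standardize = FALSE, n_bins = 20) {
  res <- purrr::map_dfr(unique(h$variants$chromosome), function(chr) {
    vi <- which(h$variants$chromosome == chr)
    hap <- h$haplotypes[, vi, drop = FALSE]
    pos <- h$variants$position_bp[vi]
    sc <- ihh_scan_cpp(hap, pos, min_ehh, max_gap_bp)
    n_hap <- nrow(hap)
    freq <- sc[, 4] / n_hap
    maf <- pmin(freq, 1 - freq)
    ihs <- log(sc[, 1] / sc[, 2])
    ihs[maf < min_maf | !is.finite(ihs)] <- NA_real_
    tibble(variant_id = h$variants$variant_id[vi], chromosome = chr,
           position_bp = pos, freq_alt = freq,
           ihh_ref = sc[, 1], ihh_alt = sc[, 2], ihs = ihs)
  })
  if (standardize) {
    res$ihs_raw <- res$ihs
    bins <- cut(res$freq_alt, seq(0, 1, length.out = n_bins + 1),
                include.lowest = TRUE)
    res <- res %>%
      group_by(bins = bins) %>%
      mutate(ihs = (.data$ihs_raw - mean(.data$ihs_raw, na.rm = TRUE)) /
               sd(.data$ihs_raw, na.rm = TRUE)) %>%
      ungroup() %>%
      select(-"bins")
  }
  res
}

#' Genome-wide Rsb scan between two populations
#'
#' Per marker, integrates the pooled site-specific EHH (iES) in each
#' population and takes `Rsb = ln(iES_1 / iES_2)`. Positive values mean
#' longer haplotype homozygosity around the site in population 1. Sites
#' with a zero integral in either population are `NA`.
#'
#' @param h1,h2 [haplotype_set()]s of the two populations over the same
#'   variant map.
#' @param min_ehh,max_gap_bp truncation rules, see [compute_ehh()].
#' @return Tibble `variant_id`, `chromosome`, `position_bp`, `ies_1`,
#'   `ies_2`, `rsb`.
#' @export
rsb_scan <- function(h1, h2, min_ehh = 0.05, max_gap_bp = 1e6) {
  if (!identical(h1$variants$variant_id, h2$variants$variant_id))
    stop_cs("the two populations must share one variant map")
  purrr::map_dfr(unique(h1$variants$chromosome), function(chr) {
    vi <- which(h1$variants$chromosome == chr)
    pos <- h1$variants$position_bp[vi]
    ies1 <- ies_scan_cpp(h1$haplotypes[, vi, drop = FALSE], pos, min_ehh, max_gap_bp)
    ies2 <- ies_scan_cpp(h2$haplotypes[, vi, drop = FALSE], pos, min_ehh, max_gap_bp)
    rsb <- log(ies1 / ies2)
    rsb[!is.finite(rsb)] <- NA_real_
    tibble(variant_id = h1$variants$variant_id[vi], chromosome = chr,
           position_bp = pos, ies_1 = ies1, ies_2 = ies2, rsb = rsb)
  })
}

#' Average a per-site statistic in sliding SNP windows
#'
#' Windows of `window_snps` consecutive markers advance by `step_snps`
#' per chromosome. Each window's value is the mean of its non-missing
#' per-site values; windows with fewer than `min_informative` usable
#' values are flagged unusable, as is a single trailing partial window
#' (emitted only when it still holds at least `min_informative` sites).
#'
#' @param sites tibble with `chromosome`, `position_bp` and the statistic
#'   column named by `value_col` (e.g. output of [ihs_scan()]).
#' @param value_col column to average (`"ihs"` or `"rsb"`).
#' @param window_snps,step_snps window geometry in SNPs.
#' @param min_informative minimum usable sites per window.
#' @return Tibble `chromosome`, `start_bp`, `end_bp`, `n_snp`,
#'   `n_informative`, `mean_stat`, `usable`, `tail`.
#' @export
window_statistics <- function(sites, value_col = "ihs", window_snps = 15,
                              step_snps = 7, min_informative = 8) {
  purrr::map_dfr(unique(sites$chromosome), function(chr) {
    sc <- sites[sites$chromosome == chr, ]
    sc <- sc[order(sc$position_bp), ]
    m <- nrow(sc)
    vals <- sc[[value_col]]
    rows <- list()
    for (start in seq(1L, m, by = step_snps)) {
      stop_i <- start + window_snps - 1L
      is_tail <- stop_i > m
      if (is_tail) stop_i <- m
      n_here <- stop_i - start + 1L
      if (is_tail && n_here < min_informative) break
      v <- vals[start:stop_i]
      n_inf <- sum(!is.na(v))
      rows[[length(rows) + 1L]] <- tibble(
        chromosome = chr, start_bp = sc$position_bp[start],
        end_bp = sc$position_bp[stop_i], n_snp = n_here,
        n_informative = n_inf,
        mean_stat = if (n_inf) mean(v, na.rm = TRUE) else NA_real_,
        usable = n_inf >= min_informative && !is_tail,
        tail = is_tail)
      if (is_tail) break
    }
    if (!length(rows)) {
      inform(paste0("window_statistics: chromosome ", chr,
                    " has too few usable sites; no windows"))
      return(NULL)
    }
    bind_rows(rows)
  })
}

#' Fractional-rank empirical p-values for window statistics
#'
#' Pools all usable windows genome-wide and assigns
#' right-tailed `p_i = #(mean >= mean_i) / N` or two-tailed
#' `p_i = min(1, 2 * min(#(<=), #(>=)) / N)`; ties share the more
#' conservative count. The top window of N distinct values gets `p = 1/N`
#' right-tailed, so `-log10 p = 2` marks the extreme 1% tail at N = 100.
#' Unusable windows get `NA`.
#'
#' @param windows tibble from [window_statistics()].
#' @param tail `"right"` (e.g. Rsb) or `"two"` (e.g. iHS).
#' @return The windows tibble with `p_value` and `neg_log10_p` columns.
#' @export
rank_pvalues <- function(windows, tail = c("right", "two")) {
  tail <- match.arg(tail)
  use <- windows$usable & !is.na(windows$mean_stat)
  x <- windows$mean_stat[use]
  N <- length(x)
  if (N < 2L) stop_cs("rank_pvalues needs at least 2 usable windows")
  ge <- vapply(x, function(v) sum(x >= v), numeric(1))
  le <- vapply(x, function(v) sum(x <= v), numeric(1))
  p <- if (tail == "right") ge / N else pmin(1, 2 * pmin(ge, le) / N)
  windows$p_value <- NA_real_
  windows$p_value[use] <- p
  windows$neg_log10_p <- -log10(windows$p_value)
  windows
}

#' Call candidate selection regions from significant windows
#'
#' A region is a chain of at least two significant windows
#' (`-log10 p >= threshold_neg_log10`) in genomic order on one
#' chromosome, each consecutive significant pair separated by at most
#' `max_gap_bp` (end of one window to start of the next; overlapping
#' windows always chain). Isolated significant windows are discarded. The
#' chain's peak window defines the region coordinates.
#'
#' @param windows tibble from [rank_pvalues()].
#' @param threshold_neg_log10 significance threshold on `-log10 p`.
#' @param max_gap_bp maximum gap between chained windows.
#' @param statistic label stored on the regions (e.g. `"iHS"`).
#' @return Tibble `chromosome`, `start_bp`, `end_bp`, `peak_neg_log10_p`,
#'   `n_windows`, `statistic`.
#' @export
call_candidate_regions <- function(windows, threshold_neg_log10 = 2,
                                   max_gap_bp = 1e5, statistic = "stat") {
  sig <- windows %>%
    filter(!is.na(.data$neg_log10_p),
           .data$neg_log10_p >= threshold_neg_log10) %>%
    arrange(chrom_rank(.data$chromosome), .data$start_bp)
  out <- list()
  for (chr in unique(sig$chromosome)) {
    sc <- sig[sig$chromosome == chr, ]
    if (nrow(sc) == 0L) next
    gap_break <- c(TRUE, sc$start_bp[-1] - sc$end_bp[-nrow(sc)] > max_gap_bp)
    chain <- cumsum(gap_break)
    for (cid in unique(chain)) {
      cc <- sc[chain == cid, ]
      if (nrow(cc) < 2L) next
      peak <- cc[which.max(cc$neg_log10_p), ]
      out[[length(out) + 1L]] <- tibble(
        chromosome = chr, start_bp = peak$start_bp, end_bp = peak$end_bp,
        peak_neg_log10_p = peak$neg_log10_p, n_windows = nrow(cc),
        statistic = statistic)
    }
  }
  if (!length(out))
    return(tibble(chromosome = character(), start_bp = numeric(),
                  end_bp = numeric(), peak_neg_log10_p = numeric(),
                  n_windows = integer(), statistic = character()))
  bind_rows(out)
}
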