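#' Pairwise genotypic r-squared within a distance window
#'
#' Squared Pearson correlation of genotype dosage vectors over jointly
#' non-missing samples, for every same-chromosome pair within `window_bp`.
#' Pairs involving a monomorphic vector are skipped. With `r2_floor > 0`
#' pairs below the floor are omitted (the common reporting convention);
#' use `r2_floor = 0` for decay profiling.
#'
#' @param g a [genotype_matrix()].
#' @param window_bp maximum inter-variant distance.
#' @param r2_floor omit pairs with `r2 < r2_floor` from the result.
#' @return Tibble `chromosome`, `variant_i`, `variant_j`, `distance_bp`,
#'   `r2`.
#' @export
pairwise_r2 <- function(g, window_bp = 1e6, r2_floor = 0) {
  out <- list()
  any_na <- anyNA(g$calls)
  for (chr in unique(g$variants$chromosome)) {
    vi <- which(g$variants$chromosome == chr)
    if (length(vi) < 2L) next
    pos <- g$variants$position_bp[vi]
    m <- length(vi)
    if (!any_na) {
      x <- g$calls[, vi, drop = FALSE]
      storage.mode(x) <- "double"
      sdv <- apply(x, 2, sd)
      poly <- sdv > 0
      cc <- suppressWarnings(cor(x[, poly, drop = FALSE]))
      idx <- which(poly)
      pr <- which(upper.tri(cc), arr.ind = TRUE)
      i <- idx[pr[, 1]]; j <- idx[pr[, 2]]
      d <- abs(pos[j] - pos[i])
      keep <- d <= window_bp
      r2 <- cc[pr]^2
      tb <- tibble(chromosome = chr,
                   variant_i = g$variants$variant_id[vi[pmin(i, j)]],
                   variant_j = g$variants$variant_id[vi[pmax(i, j)]],
                   distance_bp = d, r2 = r2)[keep, ]
    } else {
      rows <- list()
      for (a in seq_len(m - 1L)) {
        b <- which(pos > pos[a] & pos - pos[a] <= window_bp)
        for (bb in b) {
          r2 <- dosage_r2(g$calls[, vi[a]], g$calls[, vi[bb]])
          if (is.na(r2)) next
          rows[[length(rows) + 1L]] <- tibble(
            chromosome = chr, variant_i = g$variants$variant_id[vi[a]],
            variant_j = g$variants$variant_id[vi[bb]],
            distance_bp = pos[bb] - pos[a], r2 = r2)
        }
      }
      tb <- if (length(rows)) bind_rows(rows) else NULL
    }
    if (!is.null(tb) && nrow(tb)) out[[length(out) + 1L]] <- tb
  }
  if (!length(out))
    return(tibble(chromosome = character(), variant_i = character(),
                  variant_j = character(), distance_bp = numeric(),
                  r2 = numeric()))
  res <- bind_rows(out)
  res[!is.na(res$r2) & res$r2 >= r2_floor, ]
}

#' LD decay profile over distance bins
#'
#' Mean r-squared per inter-variant distance bin, plus the smallest bin
#' lower edge at which the mean drops below `decay_r2` (the conventional
#' "distance at which LD decays below 0.25"). Empty bins are flagged and
#' excluded from the curve.
#'
#' @param pairs unfiltered pair tibble from [pairwise_r2()] (use
#'   `r2_floor = 0`).
#' @param bin_edges_bp increasing vector of bin edges; bins are
#'   left-open/right-closed.
#' @param decay_r2 decay criterion on the bin mean.
#' @return Tibble `bin_start`, `bin_end`, `n_pairs`, `mean_r2` with
#'   attribute `decay_distance_bp` (NA if the curve never drops below the
#'   criterion).
#' @export
ld_decay_profile <- function(pairs,
                             bin_edges_bp = c(0, 5e4, 1e5, 2e5, 3e5, 5e5, 7.5e5, 1e6),
                             decay_r2 = 0.25) {
  bin <- cut(pairs$distance_bp, bin_edges_bp, right = TRUE)
  prof <- tibble(bin_start = bin_edges_bp[-length(bin_edges_bp)],
                 bin_end = bin_edges_bp[-1]) %>%
    mutate(idx = row_number()) %>%
    left_join(
      tibble(idx = as.integer(bin), r2 = pairs$r2) %>%
        group_by(.data$idx) %>%
        summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2), .groups = "drop"),
      by = "idx") %>%
    mutate(n_pairs = tidyr::replace_na(.data$n_pairs, 0L)) %>%
    select(-"idx")
  usable <- prof[prof$n_pairs > 0L, ]
  below <- usable$bin_start[!is.na(usable$mean_r2) & usable$mean_r2 < decay_r2]
  attr(prof, "decay_distance_bp") <- if (length(below)) min(below) else NA_real_
  attr(prof, "decay_r2") <- decay_r2
  prof
}

#' Effective population size from LD via the Sved equation
#'
#' For each distance bin with midpoint d, converts distance to
#' recombination fraction `c = d * cm_per_mb * 1e-8` Morgans per bp,
#' adjusts the bin's mean r-squared for sample size
#' (`r2_adj = mean_r2 - 1/(2 n)`), and inverts Sved's relation
#' `E[r2] = 1 / (alpha + 4 Ne c)`:
#' `Ne = (1/(4c)) * (1/r2_adj - alpha)`, dated `t = 1/(2c)` generations
#' ago. Bins whose adjusted r-squared gives a non-positive Ne are skipped
#' with a warning.
#'
#' @param pairs unfiltered pair tibble from [pairwise_r2()].
#' @param bin_edges_bp distance bin edges (default logarithmic 50 kb-1 Mb).
#' @param n_samples number of diploid samples behind the r2 estimates.
#' @param alpha Sved constant: 2 (no mutation) or 2.2 (with mutation).
#' @param cm_per_mb genetic map scale, centimorgans per megabase.
#' @return Tibble `bin_start`, `bin_end`, `distance_bp` (midpoint),
#'   `n_pairs`, `mean_r2`, `mean_r2_adj`, `c_morgans`, `generations_ago`,
#'   `ne`.
#' @export
estimate_ne_sved <- function(pairs,
                             bin_edges_bp = round(exp(seq(log(5e4), log(1e6), length.out = 9))),
                             n_samples, alpha = 2, cm_per_mb = 1) {
  if (n_samples < 2L) stop_cs("estimate_ne_sved needs n_samples >= 2")
  if (!alpha %in% c(2, 2.2))
    stop_cs("alpha must be 2 (no mutation) or 2.2 (with mutation)")
  bin <- cut(pairs$distance_bp, bin_edges_bp, right = TRUE)
  res <- tibble(bin_start = bin_edges_bp[-length(bin_edges_bp)],
                bin_end = bin_edges_bp[-1]) %>%
    mutate(idx = row_number()) %>%
    left_join(
      tibble(idx = as.integer(bin), r2 = pairs$r2) %>%
        group_by(.data$idx) %>%
        summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2), .groups = "drop"),
      by = "idx") %>%
    select(-"idx") %>%
    filter(.data$n_pairs > 0) %>%
    mutate(
      distance_bp = (.data$bin_start + .data$bin_end) / 2,
      mean_r2_adj = .data$mean_r2 - 1 / (2 * n_samples),
      c_morgans = .data$distance_bp * cm_per_mb * 1e-8,
      generations_ago = 1 / (2 * .data$c_morgans),
      ne = (1 / (4 * .data$c_morgans)) * (1 / .data$mean_r2_adj - alpha)
    )
  bad <- res$mean_r2_adj <= 0 | res$ne <= 0
  if (any(bad))
    warn(paste0("estimate_ne_sved: ", sum(bad),
                " bin(s) with infeasible adjusted r2 skipped"))
  res[!bad, ]
}
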