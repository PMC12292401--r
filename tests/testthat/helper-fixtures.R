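# small in-code fixtures and independent oracles shared across tests

# genotype matrix from a plain integer matrix (NA = missing)
toy_genotypes <- function(calls, positions = NULL, chromosome = "1",
                          populations = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(positions)) positions <- seq(1e5, by = 1e5, length.out = m)
  genotype_matrix(
    calls,
    tibble::tibble(variant_id = paste0("v", seq_len(m)),
                   chromosome = rep(chromosome, length.out = m),
                   position_bp = positions, allele_a = "A", allele_b = "B"),
    tibble::tibble(sample_id = paste0("s", seq_len(n)),
                   population = populations %||% rep("pop1", n))
  )
}

# haplotype set from a 0/1 matrix with 2 rows per sample
toy_haplotypes <- function(hap, positions = NULL, chromosome = "1") {
  hap <- as.matrix(hap)
  m <- ncol(hap)
  if (is.null(positions)) positions <- seq(1e4, by = 1e4, length.out = m)
  haplotype_set(
    hap,
    tibble::tibble(variant_id = paste0("v", seq_len(m)),
                   chromosome = rep(chromosome, length.out = m),
                   position_bp = positions, allele_a = "A", allele_b = "B"),
    paste0("s", seq_len(nrow(hap) / 2))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles ----

# HWE exact p by explicit enumeration over genotype tables (independent
# of the package's log-factorial implementation): probability of each
# heterozygote count computed from first principles via choose()
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  num <- sapply(hets, function(h) {
    choose(n, (na - h) / 2) * choose(n - (na - h) / 2, h) * 2^h
  })
  pr <- num / sum(num)
  obs <- pr[hets == n_ab]
  sum(pr[pr <= obs + 1e-12])
}

# brute-force ROH caller: same greedy selection discipline, but each
# candidate's maximal end found by explicit whole-window constraint checks
roh_oracle <- function(calls, pos, params) {
  state <- ifelse(is.na(calls), 2L, ifelse(calls == 1L, 1L, 0L))
  m <- length(state)
  window_ok <- function(i, j) {
    if (state[i] != 0L || state[j] != 0L) return(FALSE)
    if (sum(state[i:j] == 1L) > params$max_opp) return(FALSE)
    if (sum(state[i:j] == 2L) > params$max_miss) return(FALSE)
    if (j > i && any(diff(pos[i:j]) > params$max_gap_bp)) return(FALSE)
    TRUE
  }
  segs <- list()
  s <- 1L
  while (s <= m) {
    starts <- which(state == 0L & seq_len(m) >= s)
    if (!length(starts)) break
    i <- starts[1]
    ends <- which(sapply(seq_len(m), function(j) j >= i && window_ok(i, j)))
    e <- max(ends)
    if (e - i + 1L >= params$min_snp && pos[e] - pos[i] + 1 >= params$min_length_bp)
      segs[[length(segs) + 1L]] <- c(start_bp = pos[i], end_bp = pos[e],
                                     n_snp = e - i + 1L)
    s <- max(e + 1L, i + 1L)
  }
  if (!length(segs))
    return(data.frame(start_bp = numeric(), end_bp = numeric(), n_snp = integer()))
  as.data.frame(do.call(rbind, segs))
}

# brute-force EHH at one marker offset: fraction of carrier pairs identical
# on every marker from the core to the target (inclusive), by direct
# pairwise comparison
ehh_pairwise_oracle <- function(hap, carrier_rows, core, target) {
  rng <- core:target
  idx <- carrier_rows
  n <- length(idx)
  same <- 0
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (all(hap[idx[a], rng] == hap[idx[b], rng])) same <- same + 1
  }
  same / choose(n, 2)
}

# Hudson FST estimator for two populations of haplotype frequencies
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}
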