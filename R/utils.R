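# internal helpers shared across modules

# order chromosome labels numerically where possible ("2" < "10"), others last
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

chrom_rank <- function(chrom) {
  lev <- unique(chrom[chrom_order(chrom)])
  match(chrom, lev)
}

# TRUE for labels this package treats as autosomes: positive integers
is_autosome_label <- function(chrom) {
  grepl("^[0-9]+$", chrom) & suppressWarnings(as.integer(chrom)) >= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a fixed seed without disturbing the caller's RNG;
# seed = NULL leaves the RNG stream untouched
with_seed_or_not <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stop_cs <- function(...) abort(paste0(...), class = "capriscan_error")
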