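#' Read gene intervals from BED or GFF3
#'
#' Normalizes to 1-based inclusive coordinates internally (BED input is
#' 0-based half-open on disk) and sorts by chromosome and start. For GFF3
#' only `gene`-type features are used; the gene id is taken from the
#' `ID`/`gene_id` attribute and the name from `Name`/`gene_name`.
#'
#' @param path path to the annotation file.
#' @param format `"bed"`, `"gff3"`, or `NULL` to guess from the extension.
#' @return Tibble `gene_id`, `gene_name`, `chromosome`, `start_bp`,
#'   `end_bp`, `strand`.
#' @export
read_gene_intervals <- function(path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  if (format %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    meta <- as.data.frame(gr)
    gene_id <- meta$ID %||% meta$gene_id
    gene_name <- meta[["Name"]] %||% meta[["gene_name"]] %||% gene_id
    out <- tibble(
      gene_id = as.character(gene_id),
      gene_name = as.character(gene_name),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr),
      end_bp = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- gr$name %||% paste0("gene_", seq_along(gr))
    out <- tibble(
      gene_id = as.character(nm), gene_name = as.character(nm),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start_bp = GenomicRanges::start(gr),   # rtracklayer converts to 1-based
      end_bp = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    stop_cs("unsupported gene annotation format: ", format)
  }
  if (any(out$start_bp > out$end_bp)) stop_cs("gene interval with start > end")
  out[order(chrom_rank(out$chromosome), out$start_bp), ]
}

#' Map candidate regions to overlapping genes
#'
#' A gene is reported for a region when their 1-based inclusive intervals
#' overlap by at least 1 bp on the same chromosome. Output is ordered by
#' region, then gene start.
#'
#' @param regions tibble with `chromosome`, `start_bp`, `end_bp`
#'   (candidate regions or ROH islands).
#' @param genes tibble from [read_gene_intervals()].
#' @return Tibble: region columns (prefixed `region_`) joined with the
#'   overlapping gene rows; regions without genes are absent.
#' @export
intersect_regions_genes <- function(regions, genes) {
  if (!nrow(regions) || !nrow(genes))
    return(tibble(region_id = character(), region_chromosome = character(),
                  region_start_bp = numeric(), region_end_bp = numeric(),
                  gene_id = character(), gene_name = character(),
                  start_bp = numeric(), end_bp = numeric()))
  rg <- GenomicRanges::GRanges(
    regions$chromosome, IRanges::IRanges(regions$start_bp, regions$end_bp))
  gg <- GenomicRanges::GRanges(
    genes$chromosome, IRanges::IRanges(genes$start_bp, genes$end_bp))
  # disjoint chromosome sets between regions and genes are legitimate
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rg, gg))
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- bind_cols(
    tibble(
      region_id = sprintf("%s:%d-%d", regions$chromosome[ri],
                          as.integer(regions$start_bp[ri]),
                          as.integer(regions$end_bp[ri])),
      region_chromosome = regions$chromosome[ri],
      region_start_bp = regions$start_bp[ri],
      region_end_bp = regions$end_bp[ri]
    ),
    genes[gi, c("gene_id", "gene_name", "start_bp", "end_bp")]
  )
  out[order(ri, out$start_bp), ]
}

#' Read GMT-style gene sets
#'
#' @param path GMT file (term, description, then member genes per line).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric (over-representation) enrichment of gene sets
#'
#' One-sided upper-tail hypergeometric p per term, testing whether the
#' region gene list overlaps the term more than expected from drawing the
#' same number of genes from the universe; Benjamini-Hochberg adjusted
#' p-values across terms are also reported. Term gene lists are first
#' intersected with the universe.
#'
#' @param region_genes character vector of genes hit by candidate regions
#'   (must be a subset of `universe`).
#' @param gene_sets named list of character vectors (term -> genes).
#' @param universe character vector: the gene background.
#' @return Tibble `term`, `term_size`, `n_region_genes`, `overlap`,
#'   `p_value`, `p_adjusted`, sorted by p.
#' @export
hypergeometric_enrichment <- function(region_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_cs("empty gene universe")
  extra <- setdiff(region_genes, universe)
  if (length(extra))
    stop_cs("region genes not in universe: ", paste(head(extra, 3), collapse = ", "))
  region_genes <- unique(region_genes)
  k <- length(region_genes)
  res <- purrr::imap_dfr(gene_sets, function(genes, term) {
    in_universe <- intersect(unique(genes), universe)
    q <- length(intersect(region_genes, in_universe))
    m <- length(in_universe)
    p <- phyper(q - 1, m, length(universe) - m, k, lower.tail = FALSE)
    tibble(term = term, term_size = m, n_region_genes = k,
           overlap = q, p_value = p)
  })
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  arrange(res, .data$p_value)
}

#' DAVID-style enrichment score of a term cluster
#'
#' Minus log10 of the geometric mean of the member p-values; a score of
#' 1.3 corresponds to a geometric-mean p of 0.05. Monotone decreasing in
#' every member p.
#'
#' @param p_values p-values of the cluster members, each in (0, 1].
#' @return The enrichment score (a single number).
#' @export
enrichment_score <- function(p_values) {
  if (!length(p_values)) stop_cs("enrichment_score needs at least one p-value")
  if (any(p_values <= 0 | p_values > 1)) stop_cs("p-values must lie in (0, 1]")
  -log10(exp(mean(log(p_values))))
}
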