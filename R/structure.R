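#' Principal component analysis of genotype dosages
#'
#' Mean-centers each variant (optionally scales to unit variance), imputes
#' missing calls to the variant mean, and decomposes by SVD. Each
#' component is oriented so its largest-magnitude loading is positive,
#' making score signs reproducible.
#'
#' @param g a [genotype_matrix()].
#' @param n_components number of components to return.
#' @param scale. scale variants to unit variance (off by default; the
#'   default matches plain mean-centered PCA of dosages).
#' @return An object of class `capri_pca`: `scores` tibble (sample sheet +
#'   `PC1..PCk`), `variance_fraction`, `rotation`.
#' @export
pca_genotypes <- function(g, n_components = 10, scale. = FALSE) {
  n <- nrow(g$calls)
  if (n < 2L) stop_cs("PCA needs at least 2 samples")
  if (n_components > n)
    stop_cs("requested ", n_components, " components from ", n, " samples")
  x <- g$calls
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, colMeans(x))
  if (scale.) {
    sdv <- apply(x, 2, sd)
    sdv[sdv == 0] <- 1
    x <- sweep(x, 2, sdv, "/")
  }
  sv <- svd(x, nu = n_components, nv = n_components)
  total_var <- sum(x^2) / (n - 1)
  var_frac <- (sv$d^2 / (n - 1)) / total_var
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rotation <- sv$v
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(n_components)) {
    if (rotation[which.max(abs(rotation[, k])), k] < 0) {
      rotation[, k] <- -rotation[, k]
      scores[, k] <- -scores[, k]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(
    list(
      scores = bind_cols(g$samples, as_tibble(scores)),
      variance_fraction = var_frac[seq_len(n_components)],
      variance_fraction_all = var_frac,
      rotation = rotation
    ),
    class = "capri_pca"
  )
}

#' @exportS3Method base::print
print.capri_pca <- function(x, ...) {
  k <- length(x$variance_fraction)
  cat("<capri_pca> ", nrow(x$scores), " samples, ", k, " components\n", sep = "")
  cat("  variance explained: ",
      paste(sprintf("PC%d %.1f%%", seq_len(min(k, 4)),
                    100 * x$variance_fraction[seq_len(min(k, 4))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.capri_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @export
glance.capri_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         n_components = length(x$variance_fraction),
         var_explained = sum(x$variance_fraction))
}

#' Per-sample observed homozygosity
#'
#' Fraction of non-missing calls that are homozygous; breed means are
#' means of per-sample values.
#'
#' @param g a [genotype_matrix()].
#' @return Tibble `sample_id`, `population`, `n_obs`, `ho`.
#' @export
observed_homozygosity <- function(g) {
  nobs <- rowSums(!is.na(g$calls))
  if (any(nobs == 0L))
    stop_cs("sample(s) with no non-missing calls: ",
            paste(head(g$samples$sample_id[nobs == 0], 3), collapse = ", "))
  hom <- rowSums(g$calls != 1L, na.rm = TRUE)
  tibble(sample_id = g$samples$sample_id, population = g$samples$population,
         n_obs = unname(nobs), ho = unname(hom / nobs))
}

#' Fit the admixture model by EM
#'
#' Maximizes the binomial admixture log-likelihood
#' `L = sum_ij [ g_ij log p_ij + (2 - g_ij) log(1 - p_ij) ]` with
#' `p_ij = sum_k q_ik f_kj` over ancestry fractions Q (samples x K, rows
#' on the simplex) and cluster allele frequencies F (K x variants), by
#' plain EM from a random Dirichlet/uniform start. Missing calls are
#' excluded from the likelihood (no imputation). The log-likelihood is
#' non-decreasing across iterations.
#'
#' @param g a [genotype_matrix()].
#' @param K number of ancestral clusters, `1 <= K <= n_samples`.
#' @param seed seed for the random start.
#' @param max_iter,tol stopping rule: stop when the log-likelihood gain
#'   drops below `tol` or after `max_iter` iterations.
#' @return An object of class `capri_admixture`: `K`, `Q` (tibble), `F`
#'   (matrix K x variants), `loglik`, `loglik_trace`, `n_iter`.
#' @export
admixture_em <- function(g, K, seed = 1L, max_iter = 300, tol = 1e-4) {
  n <- nrow(g$calls); m <- ncol(g$calls)
  if (K < 1L) stop_cs("K must be >= 1")
  if (K > n) stop_cs("K cannot exceed the number of samples")
  alt_count <- colSums(g$calls, na.rm = TRUE)
  mono <- alt_count == 0L | alt_count == 2L * colSums(!is.na(g$calls))
  if (all(mono)) stop_cs("all variants are monomorphic; admixture model is degenerate")

  G <- g$calls
  W <- !is.na(G)
  G0 <- ifelse(W, G, 0L)
  storage.mode(G0) <- "double"

  fit <- with_seed_or_not(seed, {
    Q <- matrix(rexp(n * K), n, K)
    Q <- Q / rowSums(Q)
    freq <- colSums(G0) / pmax(1, 2 * colSums(W))
    F <- matrix(pmin(pmax(
      rep(freq, each = K) + runif(K * m, -0.1, 0.1), 0.01), 0.99), K, m)
    em_admixture_loop(G0, W, Q, F, max_iter, tol)
  })

  structure(
    list(
      K = as.integer(K),
      Q = bind_cols(g$samples[, c("sample_id", "population")],
                    as_tibble(`colnames<-`(fit$Q, paste0("Q", seq_len(K))))),
      F = fit$F,
      loglik = fit$loglik[length(fit$loglik)],
      loglik_trace = fit$loglik,
      n_iter = length(fit$loglik),
      variant_id = g$variants$variant_id
    ),
    class = "capri_admixture"
  )
}

em_admixture_loop <- function(G0, W, Q, F, max_iter, tol) {
  n <- nrow(G0); K <- nrow(F)
  Wn <- W * 1
  two_m_i <- 2 * rowSums(Wn)
  ll <- numeric(0)
  eps <- 1e-9
  for (it in seq_len(max_iter)) {
    P <- Q %*% F
    P <- pmin(pmax(P, eps), 1 - eps)
    llc <- sum((G0 * log(P) + (2 * Wn - G0) * log(1 - P))[W])
    ll <- c(ll, llc)
    if (it > 1 && (llc - ll[it - 1]) < tol) break
    Ga <- G0 / P
    Gb <- (2 * Wn - G0) / (1 - P)
    Qn <- matrix(0, n, K); Fn <- F
    for (k in seq_len(K)) {
      fa <- Ga %*% F[k, ]          # n x 1
      fb <- Gb %*% (1 - F[k, ])
      Qn[, k] <- Q[, k] * (fa + fb) / two_m_i
      na_k <- F[k, ] * as.vector(crossprod(Ga, Q[, k]))
      nb_k <- (1 - F[k, ]) * as.vector(crossprod(Gb, Q[, k]))
      Fn[k, ] <- na_k / pmax(na_k + nb_k, eps)
    }
    Q <- Qn / rowSums(Qn)
    F <- pmin(pmax(Fn, eps), 1 - eps)
  }
  list(Q = Q, F = F, loglik = ll)
}

#' @exportS3Method base::print
print.capri_admixture <- function(x, ...) {
  cat("<capri_admixture> K = ", x$K, ", ", nrow(x$Q), " samples, ",
      length(x$variant_id), " variants\n", sep = "")
  cat("  log-likelihood ", format(x$loglik, digits = 10), " after ",
      x$n_iter, " EM iterations\n", sep = "")
  invisible(x)
}

#' @export
tidy.capri_admixture <- function(x, ...) {
  tidyr::pivot_longer(x$Q, dplyr::starts_with("Q"),
                      names_to = "cluster", values_to = "ancestry")
}

#' @export
glance.capri_admixture <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, n_iter = x$n_iter,
         cv_error = attr(x, "cv_error") %||% NA_real_)
}

#' Masked-entry cross-validation error for an admixture fit
#'
#' Partitions the non-missing genotype cells into folds, masks each fold
#' in turn, refits the model, and scores the masked dosages against their
#' predictions `2 * sum_k q_ik f_kj` by root-mean-square error. The K with
#' the lowest error is the supported cluster count. A partition that masks
#' every observation of some variant is redrawn (with a message).
#'
#' @param g a [genotype_matrix()].
#' @param K number of clusters.
#' @param folds number of folds (>= 2).
#' @param seed seed for partitioning and the EM starts.
#' @param ... passed to [admixture_em()].
#' @return Mean RMSE over folds (a single number).
#' @export
admixture_cv_error <- function(g, K, folds = 5, seed = 1L, ...) {
  if (folds < 2L) stop_cs("folds must be >= 2")
  cells <- which(!is.na(g$calls))
  with_seed_or_not(seed, {
    fold_of <- NULL
    for (attempt in 1:20) {
      fo <- sample(rep_len(seq_len(folds), length(cells)))
      ok <- TRUE
      for (f in seq_len(folds)) {
        masked <- g$calls
        masked[cells[fo == f]] <- NA_integer_
        if (any(colSums(!is.na(masked)) == 0L)) { ok <- FALSE; break }
      }
      if (ok) { fold_of <- fo; break }
      inform("admixture_cv_error: fold left a variant with no data; redrawing partition")
    }
    if (is.null(fold_of)) stop_cs("could not draw a valid CV partition")
    errs <- numeric(folds)
    for (f in seq_len(folds)) {
      gm <- g
      idx <- cells[fold_of == f]
      gm$calls[idx] <- NA_integer_
      fit <- admixture_em(gm, K, seed = sample.int(1e6, 1), ...)
      Qm <- as.matrix(fit$Q[, paste0("Q", seq_len(K)), drop = FALSE])
      pred <- 2 * (Qm %*% fit$F)
      errs[f] <- sqrt(mean((g$calls[idx] - pred[idx])^2))
    }
    mean(errs)
  })
}

#' Scan cluster counts and pick the cross-validation optimum
#'
#' @param g a [genotype_matrix()].
#' @param k_range integer vector of K values to try.
#' @param folds,seed as in [admixture_cv_error()].
#' @param ... passed to [admixture_em()].
#' @return Tibble `K`, `loglik`, `cv_error`, with attribute `best_k`.
#' @export
admixture_scan_k <- function(g, k_range = 1:5, folds = 5, seed = 1L, ...) {
  res <- purrr::map_dfr(k_range, function(k) {
    fit <- admixture_em(g, k, seed = seed + k, ...)
    tibble(K = k, loglik = fit$loglik,
           cv_error = admixture_cv_error(g, k, folds = folds, seed = seed + 100L + k, ...))
  })
  attr(res, "best_k") <- res$K[which.min(res$cv_error)]
  res
}

#' Two-sample Mann-Whitney U comparison
#'
#' Two-sided Mann-Whitney U via [stats::wilcox.test()]: exact null when
#' the smaller group has at most 8 values and there are no ties, normal
#' approximation with tie correction otherwise.
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @return Tibble `u_statistic`, `p_value`, `method`.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop_cs("both groups must contain at least one value")
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- min(length(values_a), length(values_b)) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = "two.sided",
                exact = exact, correct = !exact)
  )
  tibble(u_statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (exact) "exact" else "normal approximation, tie-corrected")
}
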