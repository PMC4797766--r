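#' @title Expression-stability algorithms
#' @description The four classical reference-gene stability measures operate
#'   on a complete Cq matrix (samples x genes). All four are "lower is more
#'   stable", and ranks use competition ranking (ties share the best rank:
#'   1, 1, 3).
#' @name stability-algorithms
NULL

new_stability_result <- function(algorithm, values, extra = list()) {
  ranks <- rank_values(values)
  structure(c(list(algorithm = algorithm, values = values, ranks = ranks),
              extra),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  label <- c(delta_ct = "comparative delta-Ct", genorm = "geNorm M",
             normfinder = "NormFinder", bestkeeper = "BestKeeper")[x$algorithm]
  cat(sprintf("%s stability (%d genes; lower = more stable)\n",
              label, length(x$values)))
  ord <- order(x$ranks, names(x$values))
  print(data.frame(gene = names(x$values)[ord],
                   value = round(unname(x$values[ord]), 3),
                   rank = unname(x$ranks[ord]), row.names = NULL))
  if (!is.null(x$v_series)) {
    cat("Pairwise variation V(n/n+1):\n")
    print(data.frame(n = x$v_series$n, v = round(x$v_series$v, 3),
                     row.names = NULL))
  }
  invisible(x)
}

# SD (n-1) of Cq differences for every unordered gene pair.
pairwise_sd_matrix <- function(m) {
  G <- ncol(m)
  out <- matrix(0, G, G, dimnames = list(colnames(m), colnames(m)))
  for (g in seq_len(G - 1L)) for (k in (g + 1L):G) {
    s <- stats::sd(m[, g] - m[, k])
    out[g, k] <- out[k, g] <- s
  }
  out
}

#' Comparative delta-Ct stability
#'
#' For every gene pair, the SD across samples of their Cq difference is
#' computed; a gene's score is the mean of these pair SDs over all partner
#' genes. Genes whose Cq difference to every partner stays constant across
#' samples (stably expressed, or co-regulated) score low.
#'
#' @param x a complete [cq_matrix] (or plain matrix, samples x genes) with at
#'   least 2 genes and 2 samples.
#' @return A `stability_result` with per-gene `values` and `ranks`.
#' @export
delta_ct_stability <- function(x) {
  m <- as.matrix(as_cq(x))
  stopifnot_complete(m, "delta_ct_stability")
  if (ncol(m) < 2L) stop("need at least 2 genes")
  if (nrow(m) < 2L) stop("need at least 2 samples")
  V <- pairwise_sd_matrix(m)
  values <- rowSums(V) / (ncol(m) - 1L)
  new_stability_result("delta_ct", values)
}

#' geNorm stability (M value) with pairwise variation V
#'
#' Expression is converted to relative quantities
#' \eqn{Q_{ig} = b^{Cq_{min,g} - Cq_{ig}}} (amplification-factor base `b`,
#' default 2 for efficiency-corrected Cq). A gene's M value is the mean,
#' over all partner genes, of the SD across samples of
#' \eqn{\log_2(Q_g/Q_k)}. The gene with the highest M is excluded and M
#' values are recomputed among the remaining genes, repeatedly, until two
#' genes remain; those two share the final M and rank 1 (the next gene ranks
#' 3). M below 1.5 is the conventional "acceptably stable" cut-off.
#'
#' The pairwise variation series V(n/n+1) is the SD across samples of
#' \eqn{\log_2(NF_n/NF_{n+1})}, where \eqn{NF_n} is the per-sample geometric
#' mean of Q over the n top-ranked genes; the smallest n with V below 0.15
#' is the recommended number of reference genes (see
#' [recommend_gene_count()]).
#'
#' @param x a complete [cq_matrix], at least 3 genes and 2 samples.
#' @param amp_factor_base relative-quantity base (2 = perfect doubling).
#' @return A `stability_result` with, additionally, `trace` (genes in
#'   exclusion order, least stable first), `v_series` (data.frame `n`, `v`)
#'   and `initial_m` (M values of the first, all-gene step; with base 2
#'   these equal the comparative delta-Ct scores).
#' @export
genorm <- function(x, amp_factor_base = 2) {
  m <- as.matrix(as_cq(x))
  stopifnot_complete(m, "genorm")
  G <- ncol(m)
  if (G < 3L) stop("geNorm stepwise exclusion needs at least 3 genes")
  if (nrow(m) < 2L) stop("need at least 2 samples")
  # log2 relative quantities; per-gene column shifts cancel in all SDs of
  # differences, so the minima subtraction only anchors Q in [0, 1].
  lq <- sweep(-m, 2L, -apply(m, 2L, min)) * log2(amp_factor_base)

  genes <- colnames(m)
  initial_m <- genorm_m(lq)
  remaining <- genes
  values <- stats::setNames(numeric(G), genes)
  trace <- character()
  while (length(remaining) > 2L) {
    M <- genorm_m(lq[, remaining, drop = FALSE])
    worst <- max(M)
    cand <- names(M)[M == worst]
    drop_gene <- sort(cand)[length(cand)]  # tie: alphabetically last goes
    values[drop_gene] <- M[[drop_gene]]
    trace <- c(trace, drop_gene)
    remaining <- setdiff(remaining, drop_gene)
  }
  final_m <- stats::sd(lq[, remaining[[1L]]] - lq[, remaining[[2L]]])
  values[remaining] <- final_m

  # ranks: final pair shares rank 1; then 3, 4, ... in reverse exclusion order
  ranks <- stats::setNames(integer(G), genes)
  ranks[remaining] <- 1L
  ranks[rev(trace)] <- seq.int(3L, length.out = length(trace))

  order_best_first <- c(sort(remaining), rev(trace))
  v_series <- genorm_v_series(lq[, order_best_first, drop = FALSE])
  res <- new_stability_result("genorm", values,
                              extra = list(trace = trace, v_series = v_series,
                                           initial_m = initial_m))
  res$ranks <- ranks  # shared rank 1 for the final pair, then 3, 4, ...
  res
}

# M values for a set of >= 2 genes given log2 relative quantities.
genorm_m <- function(lq) {
  V <- pairwise_sd_matrix(lq)
  stats::setNames(rowSums(V) / (ncol(lq) - 1L), colnames(lq))
}

genorm_v_series <- function(lq_ordered) {
  G <- ncol(lq_ordered)
  if (G < 3L) return(data.frame(n = integer(), v = numeric()))
  # log2 NF_n = per-sample mean of log2 Q over the n top-ranked genes
  nf <- function(n) rowMeans(lq_ordered[, seq_len(n), drop = FALSE])
  ns <- 2:(G - 1L)
  v <- vapply(ns, function(n) stats::sd(nf(n) - nf(n + 1L)), numeric(1))
  data.frame(n = ns, v = v)
}

#' NormFinder model-based stability
#'
#' Models log-scale expression \eqn{y_{ig} = -Cq_{ig}} as an additive gene
#' effect plus sample effect plus gene-specific noise,
#' \eqn{y_{ig} = \alpha_g + \beta_i + \epsilon_{ig}}, and reports each
#' gene's estimated noise SD \eqn{\hat\sigma_g} as its stability value.
#' The sample effect \eqn{\beta_i} absorbs shared RNA-input / RT-yield
#' variation, which therefore does not penalise any gene.
#'
#' The single-group estimator is a moment estimator: with \eqn{v_g} the
#' sample variance (over samples) of the doubly-centered residuals
#' \eqn{r_{ig} = y_{ig} - \bar y_{i.} - \bar y_{.g} + \bar y_{..}},
#' \deqn{\hat\sigma^2_g = \left(v_g - \frac{\sum_k v_k}{G(G-1)}\right)
#'   \frac{G}{G-2},} floored at zero. When `groups` is supplied the same
#' estimator is applied within each group and the per-gene variances are
#' pooled by their degrees of freedom (the intergroup-variation term of the
#' full multi-group method is out of scope).
#'
#' @param x a complete [cq_matrix], at least 3 genes.
#' @param groups optional factor of condition labels, one per sample; each
#'   group needs at least 2 samples.
#' @return A `stability_result`; `sigma2` holds the variance estimates.
#' @export
normfinder_stability <- function(x, groups = NULL) {
  m <- as.matrix(as_cq(x))
  stopifnot_complete(m, "normfinder_stability")
  G <- ncol(m)
  if (G < 3L) stop("NormFinder variance separation needs at least 3 genes")
  if (nrow(m) < 2L) stop("need at least 2 samples")
  y <- -m
  if (is.null(groups)) {
    sigma2 <- normfinder_sigma2(y)
  } else {
    groups <- as.factor(groups)
    if (length(groups) != nrow(m)) stop("groups must have one label per sample")
    tab <- table(groups)
    if (any(tab < 2L)) stop("each group needs at least 2 samples")
    num <- stats::setNames(numeric(G), colnames(m))
    den <- 0
    for (g in levels(groups)) {
      idx <- which(groups == g)
      w <- length(idx) - 1L
      num <- num + w * normfinder_sigma2(y[idx, , drop = FALSE])
      den <- den + w
    }
    sigma2 <- num / den
  }
  new_stability_result("normfinder", sqrt(sigma2),
                       extra = list(sigma2 = sigma2))
}

normfinder_sigma2 <- function(y) {
  G <- ncol(y)
  r <- sweep(sweep(y, 1L, rowMeans(y)), 2L, colMeans(y)) + mean(y)
  v <- apply(r, 2L, stats::var)
  pmax((v - sum(v) / (G * (G - 1))) * G / (G - 2), 0)
}

#' BestKeeper dispersion stability
#'
#' Per-gene dispersion of Cq across samples: the sample SD by default, or
#' the mean absolute deviation about the arithmetic mean (`"mad"`, the
#' descriptor of the original BestKeeper tool). Unlike the relative-quantity
#' methods, BestKeeper works on Cq directly, so shared sample-to-sample
#' shifts (RNA input) count against every gene. Dispersion below 1 cycle is
#' the conventional "stably expressed" gate.
#'
#' The BestKeeper index (per-sample geometric mean of Cq over all genes) and
#' each gene's Pearson correlation with it are reported alongside, but do
#' not enter the ranking.
#'
#' @param x a complete [cq_matrix].
#' @param dispersion `"sd"` (default) or `"mad"`.
#' @return A `stability_result` with `index` (per-sample) and
#'   `index_correlation` (per-gene Pearson r).
#' @export
bestkeeper <- function(x, dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  m <- as.matrix(as_cq(x))
  stopifnot_complete(m, "bestkeeper")
  if (nrow(m) < 2L) stop("need at least 2 samples")
  values <- switch(dispersion,
    sd = apply(m, 2L, stats::sd),
    mad = apply(m, 2L, function(v) mean(abs(v - mean(v)))))
  index <- exp(rowMeans(log(m)))
  r <- apply(m, 2L, function(v)
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, index))
  new_stability_result("bestkeeper", values,
                       extra = list(dispersion = dispersion, index = index,
                                    index_correlation = r))
}
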