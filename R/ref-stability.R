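#' Fit reference-gene stability on a Cq matrix
#'
#' The main entry point of the package. Runs the requested stability
#' algorithms on a complete Cq matrix and aggregates their ranks into the
#' comprehensive (geometric-mean) ranking. Samples with missing cells are
#' dropped with a warning before fitting.
#'
#' @param x a [cq_matrix] or plain numeric matrix (samples x genes).
#'   Efficiency-corrected Cq (see [correct_cq()]) is the intended input for
#'   the relative-quantity methods; raw Cq is also accepted.
#' @param methods subset of `"delta_ct"`, `"bestkeeper"`, `"normfinder"`,
#'   `"genorm"` (default: all four).
#' @param groups optional condition labels for NormFinder.
#' @param amp_factor_base geNorm relative-quantity base (default 2).
#' @param dispersion BestKeeper dispersion, `"sd"` or `"mad"`.
#' @param v_cutoff pairwise-variation cut-off for the recommended
#'   reference-gene count (default 0.15).
#' @param exclude genes to annotate as unsuitable in the recommendation
#'   (advisory; ranks are never altered).
#' @return An object of class `ref_stability` with components `results`
#'   (named list of `stability_result`), `ranking`
#'   (`comprehensive_ranking`, when >= 2 algorithms), `v_series`,
#'   `recommended_n` (when geNorm ran), `expression`
#'   ([summarize_expression()], raw-scale input only), `n_samples`,
#'   `genes`, `scale` and `call`. Methods: `print`, `summary`, `coef`
#'   (stability values), `ranks`, `plot`.
#' @examples
#' sim <- generate_cq_dataset(synthetic_truth(seed = 7), n_samples = 30)
#' fit <- ref_stability(sim$matrix)
#' fit
#' coef(fit)[, "genorm"]
#' @export
ref_stability <- function(x,
                          methods = c("delta_ct", "bestkeeper", "normfinder", "genorm"),
                          groups = NULL, amp_factor_base = 2,
                          dispersion = c("sd", "mad"), v_cutoff = 0.15,
                          exclude = NULL) {
  dispersion <- match.arg(dispersion)
  known <- c("delta_ct", "bestkeeper", "normfinder", "genorm")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop(sprintf("unknown method: %s (known: %s)",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  x <- as_cq(x)
  if (anyNA(unclass(x))) x <- drop_incomplete_samples(x)
  results <- list()
  for (m in methods)
    results[[m]] <- switch(m,
      delta_ct = delta_ct_stability(x),
      bestkeeper = bestkeeper(x, dispersion = dispersion),
      normfinder = normfinder_stability(x, groups = groups),
      genorm = genorm(x, amp_factor_base = amp_factor_base))
  ranking <- NULL
  if (length(results) > 1L) {
    rank_tab <- do.call(cbind, lapply(results, function(s)
      s$ranks[sort(names(s$values))]))
    ranking <- comprehensive_rank(rank_tab)
  }
  v_series <- results$genorm$v_series
  recommended_n <- if (!is.null(v_series) && nrow(v_series))
    suppressWarnings(recommend_gene_count(v_series, cutoff = v_cutoff))
  expression <- if (cq_scale(x) == "raw") summarize_expression(x)
  structure(list(results = results, ranking = ranking, v_series = v_series,
                 recommended_n = recommended_n, expression = expression,
                 n_samples = nrow(x), genes = colnames(x),
                 scale = cq_scale(x), exclude = exclude,
                 call = match.call()),
            class = "ref_stability")
}

#' @export
print.ref_stability <- function(x, ...) {
  cat(sprintf("Reference-gene stability fit: %d genes, %d samples (%s Cq)\n",
              length(x$genes), x$n_samples, x$scale))
  cat("Algorithms:", paste(names(x$results), collapse = ", "), "\n")
  if (!is.null(x$ranking)) {
    top <- utils::head(x$ranking$gene, 3L)
    cat(sprintf("Most stable (comprehensive): %s\n", paste(top, collapse = ", ")))
  }
  if (!is.null(x$recommended_n))
    cat(sprintf("Recommended number of reference genes: %d (V cut-off rule)\n",
                x$recommended_n))
  invisible(x)
}

#' @export
summary.ref_stability <- function(object, ...) {
  build_report(object$results, ranking = object$ranking,
               expression = object$expression,
               recommended_n = object$recommended_n,
               exclude = object$exclude)
}

#' @export
coef.ref_stability <- function(object, ...) {
  genes <- sort(object$genes)
  vapply(object$results, function(s) s$values[genes],
         numeric(length(genes)))
}

#' Per-algorithm and final ranks of a stability fit
#'
#' @param object a `ref_stability` fit.
#' @return Integer matrix (genes x algorithms), with a `final` column when a
#'   comprehensive ranking exists.
#' @export
ranks <- function(object) UseMethod("ranks")

#' @export
ranks.ref_stability <- function(object) {
  genes <- sort(object$genes)
  out <- vapply(object$results, function(s) s$ranks[genes],
                integer(length(genes)))
  if (!is.null(object$ranking))
    out <- cbind(out,
                 final = object$ranking$final_rank[match(genes, object$ranking$gene)])
  out
}

#' Plot a stability fit
#'
#' Left: comprehensive geometric-mean score per gene (or the single
#' algorithm's values), most stable first. Right (when geNorm ran): the
#' pairwise-variation series with the 0.15 cut-off line.
#'
#' @param x a `ref_stability` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ref_stability <- function(x, ...) {
  has_v <- !is.null(x$v_series) && nrow(x$v_series) > 0L
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  if (has_v) graphics::par(mfrow = c(1, 2))
  if (!is.null(x$ranking)) {
    graphics::barplot(stats::setNames(x$ranking$geomean, x$ranking$gene),
                      las = 2, ylab = "geometric mean of ranks",
                      main = "Comprehensive stability", ...)
  } else {
    s <- x$results[[1L]]
    ord <- order(s$ranks)
    graphics::barplot(s$values[ord], las = 2, ylab = "stability value",
                      main = s$algorithm, ...)
  }
  if (has_v) {
    graphics::plot(x$v_series$n, x$v_series$v, type = "b", pch = 19,
                   xlab = "n", ylab = "V(n/n+1)",
                   main = "Pairwise variation")
    graphics::abline(h = 0.15, lty = 2)
  }
  invisible(x)
}
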