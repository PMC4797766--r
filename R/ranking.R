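#' Competition ranking of stability values
#'
#' Ascending competition ranks: tied values share the best rank and the next
#' distinct value skips the used positions (pattern 1, 1, 3).
#'
#' @param values named numeric vector (finite).
#' @param direction `"ascending"` (lower value = rank 1, the convention for
#'   all four stability algorithms) or `"descending"`.
#' @return Integer ranks, named as `values`.
#' @examples
#' rank_values(c(RPL4 = 0.336, B2M = 0.336, ACTB = 0.345))  # 1, 1, 3
#' @export
rank_values <- function(values, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) stop("stability values must be finite")
  v <- if (direction == "ascending") values else -values
  r <- rank(v, ties.method = "min")
  stats::setNames(as.integer(r), names(values))
}

#' Comprehensive ranking by geometric mean of per-algorithm ranks
#'
#' Aggregates one rank column per algorithm into a final stability order:
#' each gene's comprehensive score is the geometric mean of its ranks, and
#' the final rank is the ascending order of that score. Ties on the
#' geometric mean are broken by the gene's best single-algorithm rank, then
#' by gene name, so the final ranking is a full permutation 1..G.
#'
#' @param ranks matrix or data.frame of positive integer ranks, genes in
#'   rows (rownames or a `gene` column), one column per algorithm; no
#'   missing entries.
#' @return A data.frame of class `comprehensive_ranking`: the rank columns
#'   plus `geomean` (full precision; conventionally printed to 2 decimals)
#'   and `final_rank`, sorted by `final_rank`.
#' @examples
#' r <- rbind(RPL4 = c(2, 7, 2, 1), PGK1 = c(1, 8, 1, 4))
#' colnames(r) <- c("delta_ct", "bestkeeper", "normfinder", "genorm")
#' comprehensive_rank(r)
#' @export
comprehensive_rank <- function(ranks) {
  if (is.data.frame(ranks)) {
    if ("gene" %in% names(ranks)) {
      rn <- as.character(ranks$gene)
      ranks <- ranks[setdiff(names(ranks), "gene")]
      rownames(ranks) <- rn
    }
    ranks <- as.matrix(ranks)
  }
  if (is.null(rownames(ranks))) stop("rank table needs gene names")
  if (anyNA(ranks)) {
    bad <- rownames(ranks)[apply(is.na(ranks), 1L, any)]
    stop(sprintf("missing algorithm rank for gene(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (any(ranks < 1)) stop("ranks must be positive integers")
  geomean <- exp(rowMeans(log(ranks)))
  best <- apply(ranks, 1L, min)
  ord <- order(geomean, best, rownames(ranks))
  out <- data.frame(gene = rownames(ranks)[ord], ranks[ord, , drop = FALSE],
                    geomean = geomean[ord],
                    final_rank = seq_len(nrow(ranks)),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("comprehensive_ranking", "data.frame")
  out
}

#' @export
print.comprehensive_ranking <- function(x, ...) {
  cat("Comprehensive stability ranking (geometric mean of algorithm ranks)\n")
  y <- as.data.frame(x)
  y$geomean <- round(y$geomean, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Recommended number of reference genes from the V series
#'
#' The geNorm pairwise-variation rule: the smallest n whose V(n/n+1) falls
#' below the cut-off (default 0.15) is the number of reference genes needed
#' for a reliable normalization factor. If no V is below the cut-off, all G
#' genes are returned with a warning.
#'
#' @param vseries data.frame with columns `n` and `v` (as produced by
#'   [genorm()]).
#' @param cutoff V cut-off (default 0.15).
#' @return Integer gene count.
#' @export
recommend_gene_count <- function(vseries, cutoff = 0.15) {
  vseries <- as.data.frame(vseries)
  if (!nrow(vseries)) stop("empty pairwise-variation series")
  vseries <- vseries[order(vseries$n), ]
  hit <- which(vseries$v < cutoff)
  if (length(hit)) return(as.integer(vseries$n[hit[[1L]]]))
  g <- as.integer(max(vseries$n) + 1L)
  warning(sprintf("no V(n/n+1) below %g; recommending all %d genes", cutoff, g))
  g
}

#' Per-gene expression summary and expression class
#'
#' Mean, min, max and range of raw Cq per gene, and the conventional
#' expression class: high expression for mean Cq below 25 cycles, low
#' otherwise (a boundary mean of exactly 25 is classed low). Pairing
#' reference genes with targets of the same expression class improves
#' normalization uniformity.
#'
#' @param x a complete raw-scale [cq_matrix].
#' @return data.frame with columns `gene`, `mean_cq`, `min_cq`, `max_cq`,
#'   `range`, `expression_class`.
#' @export
summarize_expression <- function(x) {
  x <- as_cq(x)
  m <- as.matrix(x)
  stopifnot_complete(m, "summarize_expression")
  mean_cq <- colMeans(m)
  min_cq <- apply(m, 2L, min)
  max_cq <- apply(m, 2L, max)
  data.frame(gene = colnames(m), mean_cq = mean_cq, min_cq = min_cq,
             max_cq = max_cq, range = max_cq - min_cq,
             expression_class = ifelse(mean_cq < 25, "high", "low"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the per-gene stability report
#'
#' One row per gene, sorted by final comprehensive rank, with
#' (value, rank) per algorithm — the layout of a stability-study results
#' table — plus a recommendation block: the top genes overall and per
#' expression class, and the recommended reference-gene count from the V
#' series. Genes can be flagged unsuitable on external (e.g. biological)
#' grounds; the flag annotates the recommendation text only and never alters
#' the ranks.
#'
#' @param stability list of `stability_result` objects (at least one).
#' @param ranking optional `comprehensive_ranking`; required when more than
#'   one algorithm is supplied.
#' @param expression optional [summarize_expression()] table.
#' @param recommended_n optional reference-gene count.
#' @param exclude optional character vector of genes to annotate as
#'   unsuitable (advisory only).
#' @return list of class `stability_report`: `table` (data.frame) and
#'   `recommendation` (character).
#' @export
build_report <- function(stability, ranking = NULL, expression = NULL,
                         recommended_n = NULL, exclude = NULL) {
  if (inherits(stability, "stability_result")) stability <- list(stability)
  if (!length(stability)) stop("need stability results for at least one algorithm")
  genes <- sort(names(stability[[1L]]$values))
  for (s in stability)
    if (!setequal(names(s$values), genes))
      stop("inconsistent gene sets across stability results")
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in stability) {
    tab[[paste0(s$algorithm, "_value")]] <- unname(s$values[genes])
    tab[[paste0(s$algorithm, "_rank")]] <- unname(s$ranks[genes])
  }
  if (!is.null(ranking)) {
    if (!setequal(ranking$gene, genes))
      stop("inconsistent gene sets between ranking and stability results")
    idx <- match(genes, ranking$gene)
    tab <- cbind(tab[1L],
                 geomean = ranking$geomean[idx],
                 rank = ranking$final_rank[idx],
                 tab[-1L])
    tab <- tab[order(tab$rank), ]
  } else if (length(stability) > 1L) {
    stop("a comprehensive ranking is required when aggregating several algorithms")
  } else {
    tab <- tab[order(tab[[3L]]), ]
  }
  rownames(tab) <- NULL

  top <- tab$gene
  usable <- setdiff(top, exclude)
  n_rec <- if (!is.null(recommended_n)) recommended_n else 2L
  rec <- sprintf("Recommended reference genes (top %d): %s.",
                 n_rec, paste(utils::head(usable, n_rec), collapse = ", "))
  if (!is.null(exclude) && length(intersect(exclude, top)))
    rec <- paste0(rec, sprintf(
      " Flagged as unsuitable on external grounds (ranking unchanged): %s.",
      paste(intersect(top, exclude), collapse = ", ")))
  if (!is.null(expression)) {
    cls <- stats::setNames(expression$expression_class, expression$gene)
    for (cl in c("high", "low")) {
      in_cl <- usable[cls[usable] == cl]
      if (length(in_cl))
        rec <- paste0(rec, sprintf(" Best %s-expression (mean Cq %s 25) genes: %s.",
                                   cl, if (cl == "high") "<" else ">=",
                                   paste(utils::head(in_cl, n_rec), collapse = ", ")))
    }
  }
  structure(list(table = tab, recommendation = rec), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v)
    if (all(v == as.integer(v))) v else round(v, 3))
  if ("geomean" %in% names(tab)) tab$geomean <- round(x$table$geomean, 2)
  print(tab, row.names = FALSE)
  cat("\n", x$recommendation, "\n", sep = "")
  invisible(x)
}
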