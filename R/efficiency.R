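#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Ordinary least-squares regression of Cq on log10 relative template
#' dilution. Amplification efficiency is derived from the slope as
#' \deqn{E = (10^{-1/slope} - 1) \times 100\%,}
#' so a perfect-doubling assay (slope -3.3219) gives E = 100%. A
#' non-negative slope marks the curve invalid (efficiency undefined).
#'
#' @param points data.frame with columns `log10_dilution` and `cq` (a
#'   five-point 10-fold series uses log10 dilutions 0, -1, ..., -4), or a
#'   numeric vector of log10 dilutions when `cq` is given separately.
#' @param cq optional numeric vector of Cq values.
#' @param gene gene label carried in the result.
#' @return An object of class `standard_curve`: `gene`, `slope`, `intercept`,
#'   `r2`, `efficiency_percent`, `valid`, `points`.
#' @examples
#' d <- generate_dilution_series("PGK1", true_efficiency = 95.47)
#' fit_standard_curve(d)
#' @export
fit_standard_curve <- function(points, cq = NULL, gene = "gene") {
  if (!is.null(cq)) points <- data.frame(log10_dilution = points, cq = cq)
  points <- as.data.frame(points)
  if (!all(c("log10_dilution", "cq") %in% names(points)))
    stop("standard-curve points need columns log10_dilution and cq")
  if ("gene" %in% names(points) && length(unique(points$gene)) == 1L)
    gene <- as.character(points$gene[[1L]])
  if (nrow(points) < 3L || length(unique(points$log10_dilution)) < 3L)
    stop("need at least 3 distinct dilution levels to fit a standard curve")
  fit <- stats::lm(cq ~ log10_dilution, data = points)
  slope <- unname(stats::coef(fit)[["log10_dilution"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  sst <- sum((points$cq - mean(points$cq))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else NA_real_
  valid <- slope < 0
  eff <- if (valid) (10^(-1 / slope) - 1) * 100 else NA_real_
  structure(list(gene = gene, slope = slope, intercept = intercept, r2 = r2,
                 efficiency_percent = eff, valid = valid,
                 points = points[c("log10_dilution", "cq")]),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  if (x$valid)
    cat(sprintf("Standard curve [%s]: slope %.4f, intercept %.2f, E = %.2f%%, R^2 = %.4f\n",
                x$gene, x$slope, x$intercept, x$efficiency_percent, x$r2))
  else
    cat(sprintf("Standard curve [%s]: INVALID (slope %.4f >= 0)\n", x$gene, x$slope))
  invisible(x)
}

#' Per-gene amplification-efficiency record
#'
#' @param gene gene id.
#' @param efficiency_percent amplification efficiency in percent (100 =
#'   perfect doubling).
#' @param efficiency_sd SD over repeated curve fits (optional).
#' @param r2 standard-curve R^2 (optional).
#' @return A one-row data.frame with the derived amplification factor
#'   `amp_factor = 1 + efficiency_percent/100`.
#' @export
efficiency_record <- function(gene, efficiency_percent, efficiency_sd = NA_real_,
                              r2 = NA_real_) {
  if (efficiency_percent <= -100) stop("efficiency must exceed -100%")
  data.frame(gene = gene, efficiency_percent = efficiency_percent,
             efficiency_sd = efficiency_sd, r2 = r2,
             amp_factor = 1 + efficiency_percent / 100,
             stringsAsFactors = FALSE)
}

#' Read a per-gene efficiency table
#'
#' CSV with columns `gene, efficiency_percent[, efficiency_sd][, r2]`.
#'
#' @param path file path.
#' @return data.frame with an added `amp_factor` column.
#' @export
read_efficiency_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene", "efficiency_percent") %in% names(df)))
    stop("efficiency table needs columns gene, efficiency_percent")
  df$amp_factor <- 1 + df$efficiency_percent / 100
  df
}

#' Gate an efficiency record against acceptance criteria
#'
#' The conventional assay-quality gate: efficiency within \[95, 105\]% and
#' standard-curve R^2 above 0.99.
#'
#' @param rec a `standard_curve`, an [efficiency_record()] row, or a list
#'   with `efficiency_percent` and `r2`.
#' @param e_min,e_max efficiency acceptance bounds in percent.
#' @param r2_min R^2 must strictly exceed this.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria; empty when passing).
#' @export
gate_efficiency <- function(rec, e_min = 95, e_max = 105, r2_min = 0.99) {
  e <- rec$efficiency_percent
  r2 <- rec$r2
  reasons <- character()
  if (is.na(e) || e < e_min) reasons <- c(reasons, sprintf("efficiency below %g%%", e_min))
  if (!is.na(e) && e > e_max) reasons <- c(reasons, sprintf("efficiency above %g%%", e_max))
  if (is.na(r2) || r2 <= r2_min) reasons <- c(reasons, sprintf("R^2 not above %g", r2_min))
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Efficiency-corrected Cq transform
#'
#' Re-expresses each gene's Cq values on an ideal-efficiency (doubling)
#' scale. With per-gene calibrator Cq_min (the lowest observed Cq of that
#' gene, i.e. its most expressed sample) and dCq = Cq - Cq_min, the
#' corrected value is
#' \deqn{Cq_{corr} = Cq_{min} + \Delta Cq \cdot \log_2(1 + E/100),}
#' so that \eqn{2^{-\Delta Cq_{corr}} = (1+E/100)^{-\Delta Cq}}: relative
#' quantities computed with base 2 from corrected Cq equal those computed
#' with the true amplification factor from raw Cq. At E = 100% the transform
#' is the identity, and each gene's minimum is unchanged at any E.
#'
#' Cq_min is taken per gene within the matrix being analysed, so a subset
#' analysis is self-contained.
#'
#' @param x a [cq_matrix] with scale `"raw"`.
#' @param effs efficiency table (data.frame with `gene` and
#'   `efficiency_percent` or `amp_factor` columns) or a named numeric vector
#'   of efficiency percentages.
#' @param assume_perfect if `TRUE`, genes without an efficiency record get
#'   amplification factor 2 (E = 100%) instead of raising an error.
#' @return A [cq_matrix] with scale `"corrected"`.
#' @export
correct_cq <- function(x, effs, assume_perfect = FALSE) {
  x <- as_cq(x)
  if (cq_scale(x) != "raw") stop("correct_cq expects a raw-scale Cq matrix")
  if (is.numeric(effs) && !is.null(names(effs)))
    effs <- data.frame(gene = names(effs), efficiency_percent = unname(effs))
  effs <- as.data.frame(effs)
  if (!"amp_factor" %in% names(effs))
    effs$amp_factor <- 1 + effs$efficiency_percent / 100
  amp <- effs$amp_factor[match(colnames(x), effs$gene)]
  if (anyNA(amp)) {
    missing_genes <- colnames(x)[is.na(amp)]
    if (!assume_perfect)
      stop(sprintf("no efficiency record for gene(s): %s",
                   paste(missing_genes, collapse = ", ")))
    amp[is.na(amp)] <- 2
  }
  if (any(amp <= 1)) stop("amplification factors must exceed 1")
  m <- as.matrix(x)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(is.na(col))) next
    cq_min <- min(col, na.rm = TRUE)
    m[, j] <- cq_min + (col - cq_min) * log2(amp[[j]])
  }
  cq_matrix(m, scale = "corrected", sample_meta = sample_meta(x))
}
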