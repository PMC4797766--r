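#' Construct a Cq matrix
#'
#' A `cq_matrix` is the central container of the package: a numeric matrix of
#' quantification-cycle (Cq) values with samples in rows and genes in columns,
#' carrying a `scale` flag that records whether the values are raw instrument
#' Cq or efficiency-corrected Cq, plus optional per-sample metadata (condition
#' label, animal id).
#'
#' All present values must lie in (0, 45], matching a 45-cycle qPCR protocol;
#' `NA` marks cells lost to replicate-quality flagging. Sample and gene ids
#' must be unique.
#'
#' @param values numeric matrix (samples x genes) with dimnames, or an object
#'   coercible to one.
#' @param scale `"raw"` or `"corrected"`.
#' @param sample_meta optional data.frame with one row per sample (e.g.
#'   columns `condition`, `animal_id`).
#' @return An object of class `cq_matrix` (a numeric matrix with attributes
#'   `scale` and `sample_meta`).
#' @examples
#' m <- matrix(c(20, 21, 25, 26), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("GAPDH", "PGK1")))
#' cq <- cq_matrix(m)
#' cq_scale(cq)
#' @export
cq_matrix <- function(values, scale = c("raw", "corrected"), sample_meta = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("Cq values must be numeric")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("gene_", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate gene ids")
  present <- values[!is.na(values)]
  if (length(present) && (any(present <= 0) || any(present > 45)))
    stop("Cq values must lie in (0, 45]")
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != nrow(values))
      stop("sample_meta must have one row per sample")
    rownames(sample_meta) <- rownames(values)
  }
  structure(values, class = c("cq_matrix", class(values)),
            scale = scale, sample_meta = sample_meta)
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("Cq matrix: %d samples x %d genes (scale: %s)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  if (anyNA(x))
    cat(sprintf("  %d missing cells\n", sum(is.na(x))))
  mat <- x
  attributes(mat) <- attributes(x)[c("dim", "dimnames")]
  print(utils::head(mat, 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more samples\n", nrow(x) - 6L))
  invisible(x)
}

#' @rdname cq_matrix
#' @param x a `cq_matrix`.
#' @export
cq_scale <- function(x) attr(x, "scale")

#' @rdname cq_matrix
#' @export
sample_meta <- function(x) attr(x, "sample_meta")

#' @export
as.matrix.cq_matrix <- function(x, ...) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

is_cq_matrix <- function(x) inherits(x, "cq_matrix")

as_cq <- function(x, scale = "raw") {
  if (is_cq_matrix(x)) x else cq_matrix(x, scale = scale)
}

#' Drop samples with any missing Cq cell
#'
#' The stability algorithms require a complete matrix; samples that lost a
#' cell to replicate flagging are removed up front, with a warning naming
#' them.
#'
#' @param x a `cq_matrix`.
#' @return The complete `cq_matrix`.
#' @export
drop_incomplete_samples <- function(x) {
  x <- as_cq(x)
  bad <- apply(is.na(unclass(x)), 1L, any)
  if (!any(bad)) return(x)
  warning(sprintf("dropping %d incomplete sample(s): %s",
                  sum(bad), paste(rownames(x)[bad], collapse = ", ")))
  meta <- sample_meta(x)
  cq_matrix(as.matrix(x)[!bad, , drop = FALSE], scale = cq_scale(x),
            sample_meta = if (!is.null(meta)) meta[!bad, , drop = FALSE])
}

stopifnot_complete <- function(x, what) {
  if (anyNA(unclass(x)))
    stop(sprintf("%s requires a complete Cq matrix; drop incomplete samples first (see drop_incomplete_samples())", what))
}
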