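#' Read a Cq table from a delimited text file
#'
#' Two dialects are supported. The wide layout has one row per sample: a
#' `sample_id` column, optional `condition` and `animal_id` metadata columns,
#' and one numeric column per gene; it yields a [cq_matrix] (scale `"raw"`
#' unless a `# scale=corrected` comment line precedes the header). The long
#' layout has columns `sample_id` (or `sample`), `gene`, `replicate`, `cq`,
#' one row per technical replicate, and yields a `cq_replicates` data.frame
#' for [collapse_replicates()].
#'
#' Files are comma- or tab-delimited (sniffed from the header line), UTF-8,
#' first non-comment row a header. All Cq values are validated to (0, 45].
#'
#' @param path file path.
#' @param layout `"auto"` (detect from columns), `"wide"` or `"long"`.
#' @return A [cq_matrix] (wide) or a `cq_replicates` data.frame (long).
#' @seealso [write_cq_table()], [collapse_replicates()]
#' @export
read_cq_table <- function(path, layout = c("auto", "wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  scale <- "raw"
  comments <- grep("^#", lines, value = TRUE)
  sc <- regmatches(comments, regexpr("scale=(raw|corrected)", comments))
  if (length(sc)) scale <- sub("scale=", "", sc[[1L]])
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no samples: file has no data rows")
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "sample"] <- "sample_id"
  if (layout == "auto")
    layout <- if (all(c("gene", "cq") %in% names(df))) "long" else "wide"
  if (layout == "long") parse_long_cq(df) else parse_wide_cq(df, scale)
}

parse_wide_cq <- function(df, scale) {
  if (!"sample_id" %in% names(df))
    stop("malformed header: wide layout needs a 'sample_id' column")
  if (nrow(df) == 0L) stop("no samples")
  meta_cols <- intersect(c("condition", "animal_id"), names(df))
  gene_cols <- setdiff(names(df), c("sample_id", meta_cols))
  if (!length(gene_cols)) stop("malformed header: no gene columns")
  vals <- df[gene_cols]
  for (g in gene_cols) {
    v <- suppressWarnings(as.numeric(df[[g]]))
    bad <- which(!is.na(df[[g]]) & df[[g]] != "" & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric Cq for gene %s at row %d", g, bad[[1L]]))
    out <- which(!is.na(v) & (v <= 0 | v > 45))
    if (length(out))
      stop(sprintf("Cq outside (0, 45] for gene %s at row %d", g, out[[1L]]))
    vals[[g]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(df$sample_id)
  meta <- if (length(meta_cols)) df[meta_cols]
  cq_matrix(m, scale = scale, sample_meta = meta)
}

parse_long_cq <- function(df) {
  need <- c("sample_id", "gene", "replicate", "cq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("malformed header: long layout missing column(s) %s",
                 paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) stop("no samples")
  cq <- suppressWarnings(as.numeric(df$cq))
  bad <- which(is.na(cq) & !is.na(df$cq))
  if (length(bad)) stop(sprintf("non-numeric Cq at row %d", bad[[1L]]))
  out <- which(!is.na(cq) & (cq <= 0 | cq > 45))
  if (length(out)) stop(sprintf("Cq outside (0, 45] at row %d", out[[1L]]))
  key <- paste(df$sample_id, df$gene, df$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicate (sample, gene, replicate) key at row %d", dup[[1L]]))
  res <- data.frame(sample_id = as.character(df$sample_id),
                    gene = as.character(df$gene),
                    replicate = df$replicate, cq = cq,
                    stringsAsFactors = FALSE)
  for (m in intersect(c("condition", "animal_id"), names(df)))
    res[[m]] <- df[[m]]
  class(res) <- c("cq_replicates", "data.frame")
  res
}

#' Collapse technical replicates into a Cq matrix
#'
#' Replicate Cq values for each (sample, gene) pair are averaged when their
#' standard deviation (n-1 denominator) is below `sd_threshold`; sets at or
#' above the threshold are flagged and the cell becomes missing. A singleton
#' replicate has SD 0 and is always kept. The default threshold of 0.5 cycles
#' is the conventional triplicate-quality gate.
#'
#' @param reps a `cq_replicates` data.frame (from [read_cq_table()] long
#'   layout) or any data.frame with columns `sample_id`, `gene`, `cq`.
#' @param sd_threshold replicate SD gate in cycles (default 0.5).
#' @return A [cq_matrix] (scale `"raw"`) with attribute `"flagged"`: a
#'   data.frame listing the flagged replicate sets (sample, gene, n, sd).
#' @export
collapse_replicates <- function(reps, sd_threshold = 0.5) {
  reps <- as.data.frame(reps)
  need <- c("sample_id", "gene", "cq")
  if (!all(need %in% names(reps)))
    stop("replicate table needs columns sample_id, gene, cq")
  samples <- unique(as.character(reps$sample_id))
  genes <- unique(as.character(reps$gene))
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  flagged <- list()
  key <- interaction(reps$sample_id, reps$gene, drop = TRUE, sep = "\r")
  for (grp in split(seq_len(nrow(reps)), key)) {
    v <- reps$cq[grp]
    v <- v[!is.na(v)]
    if (!length(v)) next
    s <- if (length(v) > 1L) stats::sd(v) else 0
    sid <- as.character(reps$sample_id[grp[[1L]]])
    g <- as.character(reps$gene[grp[[1L]]])
    if (s < sd_threshold) {
      m[sid, g] <- mean(v)
    } else {
      flagged[[length(flagged) + 1L]] <-
        data.frame(sample_id = sid, gene = g, n = length(v), sd = s)
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(sample_id = character(), gene = character(),
               n = integer(), sd = numeric())
  meta <- NULL
  meta_cols <- intersect(c("condition", "animal_id"), names(reps))
  if (length(meta_cols)) {
    first <- reps[!duplicated(reps$sample_id), , drop = FALSE]
    meta <- first[match(samples, first$sample_id), meta_cols, drop = FALSE]
  }
  out <- cq_matrix(m, scale = "raw", sample_meta = meta)
  attr(out, "flagged") <- flagged
  out
}

#' Plate-control quality check
#'
#' A plate control is an identical reaction repeated on every plate; a
#' consistent plate-control Cq (SD below 0.5 cycles) justifies combining data
#' from multiple plates into one data set.
#'
#' @param cq numeric vector of plate-control Cq values, one per plate (or a
#'   data.frame with a `cq` column).
#' @param sd_threshold acceptance gate in cycles (default 0.5).
#' @return A list of class `plate_control_qc`: `n`, `mean`, `sd`, `pass`.
#' @export
plate_control_qc <- function(cq, sd_threshold = 0.5) {
  if (is.data.frame(cq)) cq <- cq$cq
  cq <- as.numeric(cq[!is.na(cq)])
  if (length(cq) < 2L) stop("insufficient controls: need at least 2 plate-control Cq values")
  s <- stats::sd(cq)
  structure(list(n = length(cq), mean = mean(cq), sd = s,
                 pass = s < sd_threshold, sd_threshold = sd_threshold),
            class = "plate_control_qc")
}

#' @export
print.plate_control_qc <- function(x, ...) {
  cat(sprintf("Plate controls: n = %d, mean Cq = %.2f, SD = %.3f -> %s (gate SD < %.2g)\n",
              x$n, x$mean, x$sd, if (x$pass) "PASS" else "FAIL", x$sd_threshold))
  invisible(x)
}

#' Random subsample of a Cq matrix
#'
#' Draws `n` samples (rows) uniformly without replacement, reproducibly for a
#' given seed; the gene set and the relative sample order are preserved.
#' With `n` equal to the number of samples the input is returned unchanged.
#'
#' @param x a [cq_matrix].
#' @param n number of samples to keep.
#' @param seed integer RNG seed.
#' @return A [cq_matrix] with `n` rows.
#' @export
subsample_cq <- function(x, n, seed) {
  x <- as_cq(x)
  if (n > nrow(x)) stop(sprintf("cannot subsample %d of %d samples", n, nrow(x)))
  if (n == nrow(x)) return(x)
  idx <- sort(with_seed(seed, sample.int(nrow(x), n)))
  meta <- sample_meta(x)
  cq_matrix(as.matrix(x)[idx, , drop = FALSE], scale = cq_scale(x),
            sample_meta = if (!is.null(meta)) meta[idx, , drop = FALSE])
}

# Run code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a Cq matrix to the canonical wide CSV
#'
#' Writes a `# scale=raw|corrected` comment line, then a header
#' (`sample_id`, metadata columns, gene columns) and one row per sample.
#' Reading the file back with [read_cq_table()] reproduces ids, scale and
#' values.
#'
#' @param x a [cq_matrix].
#' @param path output file path.
#' @param digits number of decimal digits to print (default 6).
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(x, path, digits = 6) {
  x <- as_cq(x)
  df <- data.frame(sample_id = rownames(x), stringsAsFactors = FALSE)
  meta <- sample_meta(x)
  if (!is.null(meta)) df <- cbind(df, meta)
  vals <- as.data.frame(round(as.matrix(x), digits))
  df <- cbind(df, vals)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# scale=%s", cq_scale(x)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
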