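#' Ground truth for a synthetic qPCR data set
#'
#' Defines the generative model for [generate_cq_dataset()]:
#' \deqn{Cq_{ig} = \mu_g + \delta_i + \Delta_{c(i),g} + \epsilon_{ig}}
#' with a per-sample global shift \eqn{\delta_i \sim N(0, \tau)} (shared
#' RNA-input / RT-yield variation, loading 1 on every gene — exactly the
#' variation the relative-quantity stability methods are designed to
#' ignore), gene-specific noise \eqn{\epsilon_{ig} \sim N(0, \sigma_g)},
#' and optional condition-linked regulation \eqn{\Delta_{cg}} turning a
#' gene into a pseudo-housekeeper. Technical triplicates add
#' \eqn{N(0, \texttt{replicate\_sd})} on top, with occasional +2-cycle
#' outlier replicates.
#'
#' Defaults emulate a blood reference-gene study design: a 13-gene
#' candidate panel with baselines spread over Cq 22–31, noise SDs spanning
#' 0.05–0.8 cycles (the implied true stability order is ascending
#' \eqn{\sigma_g}), sample shift SD 0.5, four animals and four condition
#' classes (healthy / inflammation / skin lesion / internal disease in
#' 30:6:9:15 proportions), triplicate reactions, and 100% true
#' amplification efficiency per gene.
#'
#' @param genes gene ids (default: a 13-gene housekeeping panel).
#' @param mu per-gene baseline Cq (cycles).
#' @param sigma per-gene noise SD (cycles); ascending `sigma` = true
#'   stability order.
#' @param tau sample-shift SD (cycles).
#' @param condition_effects optional matrix (conditions x genes) of Cq
#'   shifts; 0 = unregulated.
#' @param efficiency per-gene true amplification efficiency (%).
#' @param replicate_sd technical-replicate noise SD (cycles).
#' @param outlier_rate probability that one replicate is shifted +2 cycles.
#' @param seed integer RNG seed, carried in all generated outputs.
#' @return list of class `synthetic_truth`, including `true_order`
#'   (gene names, most stable first).
#' @export
synthetic_truth <- function(genes = c("ACTB", "B2M", "GAPDH", "HPRT1", "LDHB",
                                      "PGK1", "RPL4", "RPL8", "RPL18", "RPS9",
                                      "RPS18", "TFRC", "YWHAZ"),
                            mu = seq(22, 31, length.out = length(genes)),
                            sigma = seq(0.05, 0.8, length.out = length(genes)),
                            tau = 0.5,
                            condition_effects = NULL,
                            efficiency = rep(100, length(genes)),
                            replicate_sd = 0.15,
                            outlier_rate = 0,
                            seed = 1L) {
  G <- length(genes)
  stopifnot(length(mu) == G, length(sigma) == G, length(efficiency) == G)
  if (tau < 0 || any(sigma < 0) || replicate_sd < 0)
    stop("tau, sigma and replicate_sd must be non-negative")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must be in [0, 1]")
  if (any(efficiency <= -100)) stop("efficiency must exceed -100%")
  if (!is.null(condition_effects)) {
    condition_effects <- as.matrix(condition_effects)
    if (ncol(condition_effects) != G)
      stop("condition_effects needs one column per gene")
    colnames(condition_effects) <- genes
  }
  names(mu) <- names(sigma) <- names(efficiency) <- genes
  structure(list(genes = genes, mu = mu, sigma = sigma, tau = tau,
                 condition_effects = condition_effects,
                 efficiency = efficiency, replicate_sd = replicate_sd,
                 outlier_rate = outlier_rate, seed = as.integer(seed),
                 true_order = genes[order(sigma)]),
            class = "synthetic_truth")
}

#' Generate a synthetic Cq data set with known ground truth
#'
#' Draws per-sample conditions and animals (study design proportions:
#' healthy 30, inflammation 6, skin lesion 9, internal disease 15 out of
#' 60, rescaled to `n_samples`; 4 animals round-robin), then Cq values per
#' the [synthetic_truth()] model, then technical triplicates. Deterministic
#' for a given truth seed. Optionally writes the wide and long Cq tables,
#' per-gene dilution series and the truth record to `write_dir`.
#'
#' @param truth a [synthetic_truth()].
#' @param n_samples number of biological samples (default 60).
#' @param replicates technical replicates per reaction (default 3).
#' @param write_dir optional directory for `cq_wide.csv`, `cq_long.csv`,
#'   `curves.csv`, `truth.json`.
#' @return list: `matrix` (raw [cq_matrix] of true per-sample Cq, before
#'   replicate noise), `replicates` (long `cq_replicates` table), `truth`.
#' @examples
#' sim <- generate_cq_dataset(synthetic_truth(seed = 42), n_samples = 12)
#' dim(sim$matrix)
#' @export
generate_cq_dataset <- function(truth, n_samples = 60, replicates = 3,
                                write_dir = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), n_samples >= 2, replicates >= 1)
  G <- length(truth$genes)
  with_seed(truth$seed, {
    conds <- if (!is.null(truth$condition_effects)) rownames(truth$condition_effects)
      else c("healthy", "inflammation", "skin_lesion", "internal_disease")
    base_prop <- if (length(conds) == 4L) c(30, 6, 9, 15) / 60 else
      rep(1 / length(conds), length(conds))
    counts <- round(base_prop * n_samples)
    counts[1L] <- n_samples - sum(counts[-1L])
    condition <- sample(rep(conds, counts))
    animal_id <- paste0("animal_", (seq_len(n_samples) - 1L) %% 4L + 1L)
    delta <- stats::rnorm(n_samples, 0, truth$tau)
    eps <- matrix(stats::rnorm(n_samples * G), n_samples, G) %*% diag(truth$sigma)
    m <- outer(delta, rep(1, G)) + outer(rep(1, n_samples), truth$mu) + eps
    if (!is.null(truth$condition_effects))
      m <- m + truth$condition_effects[condition, , drop = FALSE]
    dimnames(m) <- list(sprintf("sample_%02d", seq_len(n_samples)), truth$genes)

    rep_cq <- m[rep(seq_len(n_samples), each = G * replicates), ]
    long <- data.frame(
      sample_id = rep(rownames(m), each = G * replicates),
      gene = rep(rep(truth$genes, each = replicates), times = n_samples),
      replicate = rep(seq_len(replicates), times = n_samples * G),
      stringsAsFactors = FALSE)
    base_cq <- m[cbind(match(long$sample_id, rownames(m)),
                       match(long$gene, truth$genes))]
    noise <- stats::rnorm(nrow(long), 0, truth$replicate_sd)
    outlier <- stats::runif(nrow(long)) < truth$outlier_rate
    long$cq <- base_cq + noise + 2 * outlier
    long$condition <- condition[match(long$sample_id, rownames(m))]
    long$animal_id <- animal_id[match(long$sample_id, rownames(m))]
    class(long) <- c("cq_replicates", "data.frame")

    meta <- data.frame(condition = condition, animal_id = animal_id,
                       stringsAsFactors = FALSE)
    mat <- cq_matrix(m, scale = "raw", sample_meta = meta)

    curves <- do.call(rbind, lapply(truth$genes, function(g)
      generate_dilution_series(g, truth$efficiency[[g]],
                               intercept = truth$mu[[g]],
                               noise_sd = 0)))
    if (!is.null(write_dir)) {
      dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
      write_cq_table(mat, file.path(write_dir, "cq_wide.csv"))
      utils::write.csv(as.data.frame(long), file.path(write_dir, "cq_long.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(curves, file.path(write_dir, "curves.csv"),
                       row.names = FALSE, quote = FALSE)
      tr <- truth
      tr$condition_effects <- if (!is.null(tr$condition_effects))
        as.data.frame(tr$condition_effects)
      jsonlite::write_json(unclass(tr), file.path(write_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(matrix = mat, replicates = long, curves = curves, truth = truth)
  })
}

#' Generate a standard-curve dilution series
#'
#' Noiseless Cq at relative dilution d is
#' `intercept - log10(d) / log10(amp_factor)` with
#' `amp_factor = 1 + true_efficiency/100`, i.e. a line of slope
#' `-1/log10(amp_factor)` on log10 dilution (-3.3219 at 100% efficiency);
#' Gaussian noise of SD `noise_sd` is added per point. Dilution levels are
#' 1, 1/step, ..., 1/step^(levels-1).
#'
#' @param gene gene label.
#' @param true_efficiency amplification efficiency in percent.
#' @param intercept Cq of the undiluted level (log10 dilution 0).
#' @param noise_sd per-point Cq noise SD (cycles).
#' @param levels number of dilution points (>= 3, default 5).
#' @param step fold-dilution per level (default 10).
#' @param seed optional RNG seed for the noise.
#' @return data.frame `gene`, `log10_dilution`, `cq` — the input format of
#'   [fit_standard_curve()].
#' @export
generate_dilution_series <- function(gene, true_efficiency, intercept = 30,
                                     noise_sd = 0, levels = 5, step = 10,
                                     seed = NULL) {
  if (true_efficiency <= -100) stop("efficiency must exceed -100%")
  if (levels < 3) stop("need at least 3 dilution levels")
  if (step <= 1) stop("dilution step must exceed 1")
  amp <- 1 + true_efficiency / 100
  ld <- -(seq_len(levels) - 1L) * log10(step)
  slope <- -1 / log10(amp)
  cq <- intercept + slope * ld
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(levels, 0, noise_sd)
      else with_seed(seed, stats::rnorm(levels, 0, noise_sd))
    cq <- cq + noise
  }
  data.frame(gene = gene, log10_dilution = ld, cq = cq,
             stringsAsFactors = FALSE)
}
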