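#' Pipeline run configuration
#'
#' Bundles the inputs and thresholds of [run_pipeline()]. Thresholds
#' default to the conventional qPCR quality gates: replicate SD 0.5,
#' efficiency 95–105% with R^2 > 0.99, geNorm M cut-off 1.5, V cut-off
#' 0.15, expression-class boundary Cq 25.
#'
#' @param cq path to a Cq table (wide or long; see [read_cq_table()]).
#' @param efficiencies optional path to an efficiency table
#'   ([read_efficiency_table()]).
#' @param input_scale feed the algorithms `"corrected"` Cq (default; needs
#'   efficiencies or `assume_perfect`) or `"raw"` Cq.
#' @param methods stability algorithms to run.
#' @param replicate_sd_threshold,e_min,e_max,r2_min,m_cutoff,v_cutoff,expression_boundary
#'   quality-gate thresholds.
#' @param dispersion BestKeeper dispersion (`"sd"` or `"mad"`).
#' @param subsample optional number of samples to draw; requires `seed`.
#' @param seed RNG seed for subsampling.
#' @param assume_perfect treat genes without an efficiency record as
#'   perfectly efficient (factor 2).
#' @param out optional output path for the report TSV.
#' @param verbose emit `[stage] event` log messages (default TRUE).
#' @return list of class `run_config`.
#' @export
run_config <- function(cq, efficiencies = NULL,
                       input_scale = c("corrected", "raw"),
                       methods = c("delta_ct", "bestkeeper", "normfinder", "genorm"),
                       replicate_sd_threshold = 0.5,
                       e_min = 95, e_max = 105, r2_min = 0.99,
                       m_cutoff = 1.5, v_cutoff = 0.15,
                       expression_boundary = 25,
                       dispersion = "sd",
                       subsample = NULL, seed = NULL,
                       assume_perfect = FALSE, out = NULL, verbose = TRUE) {
  input_scale <- match.arg(input_scale)
  thresholds <- c(replicate_sd_threshold, e_min, e_max, r2_min, m_cutoff,
                  v_cutoff, expression_boundary)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (!is.null(subsample) && is.null(seed))
    stop("subsample requires a seed")
  structure(list(cq = cq, efficiencies = efficiencies,
                 input_scale = input_scale, methods = methods,
                 replicate_sd_threshold = replicate_sd_threshold,
                 e_min = e_min, e_max = e_max, r2_min = r2_min,
                 m_cutoff = m_cutoff, v_cutoff = v_cutoff,
                 expression_boundary = expression_boundary,
                 dispersion = dispersion,
                 subsample = subsample, seed = seed,
                 assume_perfect = assume_perfect, out = out,
                 verbose = verbose),
            class = "run_config")
}

#' Run the full stability pipeline
#'
#' Read -> collapse replicates -> efficiency-correct -> (optional)
#' subsample -> four stability algorithms -> comprehensive ranking ->
#' report. Flagged replicate sets and dropped incomplete samples are
#' logged; every log line is `[stage] event` so runs are machine-checkable.
#' Deterministic: the only randomness is the seeded subsample draw.
#'
#' @param config a [run_config()].
#' @return The [ref_stability] fit, invisibly, with the report attached as
#'   attribute `"report"`; writes the report TSV when `config$out` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, fmt, ...) {
    if (config$verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  dat <- read_cq_table(config$cq)
  if (inherits(dat, "cq_replicates")) {
    say("collapse", "collapsing %d replicate rows", nrow(dat))
    dat <- collapse_replicates(dat, sd_threshold = config$replicate_sd_threshold)
    fl <- attr(dat, "flagged")
    say("collapse", "flagged_sets=%d", nrow(fl))
  }
  say("read", "samples=%d genes=%d scale=%s", nrow(dat), ncol(dat), cq_scale(dat))
  raw <- dat
  if (config$input_scale == "corrected" && cq_scale(dat) == "raw") {
    effs <- NULL
    if (!is.null(config$efficiencies)) {
      effs <- read_efficiency_table(config$efficiencies)
      for (i in seq_len(nrow(effs))) {
        gate <- gate_efficiency(effs[i, ], config$e_min, config$e_max, config$r2_min)
        if (!gate$pass)
          say("efficiency", "gate_fail gene=%s (%s)", effs$gene[[i]],
              paste(gate$reasons, collapse = "; "))
      }
    } else if (!config$assume_perfect) {
      stop("[efficiency] corrected input scale needs an efficiency table (or assume_perfect)")
    } else {
      effs <- data.frame(gene = character(), efficiency_percent = numeric())
    }
    dat <- correct_cq(dat, effs, assume_perfect = config$assume_perfect)
    say("correct", "applied efficiency correction")
  }
  n_before <- nrow(dat)
  dat <- withCallingHandlers(drop_incomplete_samples(dat),
    warning = function(w) {
      say("qc", "%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (nrow(dat) < n_before)
    say("qc", "dropped_samples=%d", n_before - nrow(dat))
  if (!is.null(config$subsample)) {
    dat <- subsample_cq(dat, config$subsample, seed = config$seed)
    say("subsample", "n=%d seed=%d", config$subsample, config$seed)
  }
  fit <- ref_stability(dat, methods = config$methods,
                       dispersion = config$dispersion,
                       v_cutoff = config$v_cutoff)
  if (cq_scale(raw) == "raw" && !anyNA(unclass(raw)))
    fit$expression <- summarize_expression(
      if (!is.null(config$subsample)) subsample_cq(raw, config$subsample, config$seed)
      else raw)
  report <- summary(fit)
  if (!is.null(config$out)) {
    utils::write.table(report$table, config$out, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    say("report", "written %s", config$out)
  }
  say("done", "genes=%d samples=%d", length(fit$genes), fit$n_samples)
  attr(fit, "report") <- report
  invisible(fit)
}

#' Published beluga-blood stability tables
#'
#' Packaged results of a published RT-qPCR reference-gene study in beluga
#' whale blood: per-gene stability values and ranks from the four
#' algorithms plus the comprehensive geometric-mean ranking, for the full
#' 60-sample set and a random 30-sample subset, and the per-gene
#' amplification efficiencies of the 13 candidate-gene assays. Useful as
#' realistic example input for the rank-aggregation stage and for checking
#' conventional quality gates.
#'
#' @param samples 60 (full set) or 30 (subset).
#' @return `beluga_stability_table()`: data.frame with columns `gene`,
#'   `geomean`, `rank`, then `<algorithm>_value` / `<algorithm>_rank` for
#'   delta_ct, bestkeeper, normfinder and genorm.
#'   `beluga_efficiencies()`: data.frame `gene`, `efficiency_percent`,
#'   `efficiency_sd`, `r2`, `amp_factor`.
#' @examples
#' tab <- beluga_stability_table(60)
#' comprehensive_rank(tab[, c("gene", "delta_ct_rank", "bestkeeper_rank",
#'                            "normfinder_rank", "genorm_rank")])
#' @export
beluga_stability_table <- function(samples = c(60, 30)) {
  samples <- match.arg(as.character(samples[[1L]]), c("60", "30"))
  path <- system.file("extdata", sprintf("beluga_stability_%s.csv", samples),
                      package = "refstab", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname beluga_stability_table
#' @export
beluga_efficiencies <- function() {
  read_efficiency_table(system.file("extdata", "beluga_efficiency.csv",
                                    package = "refstab", mustWork = TRUE))
}
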