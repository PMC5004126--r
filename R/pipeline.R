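#' Pipeline run configuration
#'
#' Bundles every stage's settings for a reproducible end-to-end run.
#' Exactly one of `input` (CSV path) or `simulate` (a list of arguments for
#' [generate_sensor_table()], or `TRUE` for the defaults) must be given.
#'
#' @param simulate `TRUE`, or a named list of [generate_sensor_table()]
#'   arguments, or NULL.
#' @param input CSV path, or NULL.
#' @param nitrate_var Name of the variable of interest.
#' @param alignment Optional [alignment_policy] applied before detrending.
#' @param detrend A [detrend_config].
#' @param pde List: `quantile`, `subsample_cap`, `n_grid`.
#' @param mixture List: `k_min`, `k_max`, `criterion`, `tol`, `max_iter`,
#'   `n_restarts`, optional `init` (user-defined start honoured as-is).
#' @param compare List: `alpha`, `scope`.
#' @param seed Root seed; per-stage sub-seeds are derived from it.
#' @param outdir Output directory for the run artifacts.
#' @return A `run_config` object.
#' @export
run_config <- function(simulate = TRUE, input = NULL, nitrate_var = "NO3",
                       alignment = NULL, detrend = detrend_config(),
                       pde = list(), mixture = list(), compare = list(),
                       seed = 1L, outdir = tempfile("nitratemodes_run_")) {
  if (is.null(input) == is.null(simulate) ||
      (is.logical(simulate) && !simulate && is.null(input)))
    stop("exactly one of `input` and `simulate` must be given")
  mixture <- utils::modifyList(
    list(k_min = 1L, k_max = 10L, criterion = "both", tol = 1e-9,
         max_iter = 2000L, n_restarts = 5L, init = NULL), mixture)
  compare <- utils::modifyList(list(alpha = 0.01, scope = "global"), compare)
  pde <- utils::modifyList(
    list(quantile = 0.18, subsample_cap = 5000L, n_grid = 200L), pde)
  structure(list(simulate = simulate, input = input, nitrate_var = nitrate_var,
                 alignment = alignment, detrend = detrend, pde = pde,
                 mixture = mixture, compare = compare,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

# deterministic per-stage sub-seeds (kept below 2^31)
sub_seed <- function(seed, stage) (as.numeric(seed) + stage * 1000003) %% 2147483647

#' Run the whole pipeline
#'
#' simulate/read -> align -> detrend -> PDE -> mixture fit & selection ->
#' Bayes classification -> goodness of fit -> mode-conditioned comparison.
#' Writes nine artifacts into `config$outdir` (residual table, PDE curve,
#' model-selection table, fitted model, classification, GoF report,
#' comparison table, class summaries, run manifest) and returns the manifest.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with the manifest and all in-memory stage
#'   results (`table`, `detrended`, `pde`, `selection`, `fit`, `assignment`,
#'   `gof`, `comparison`, `summaries`).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$outdir, f)

  ## stage 0: input
  tab <- if (!is.null(config$input)) {
    read_timetable(config$input)
  } else {
    args <- if (is.list(config$simulate)) config$simulate else list()
    if (is.null(args$seed)) args$seed <- sub_seed(config$seed, 1L)
    do.call(generate_sensor_table, args)
  }
  if (!config$nitrate_var %in% names(tab$data))
    stop("missing nitrate column `", config$nitrate_var, "` in the input")

  ## stage 1: alignment
  if (!is.null(config$alignment)) tab <- align(tab, config$alignment)

  ## stage 2: detrend
  det <- detrend_table(tab, config$detrend)
  write_timetable(det$residual, art("residuals.csv"))

  ## stage 3: PDE of the nitrate residual
  nit <- residual_series(det, config$nitrate_var)
  curve <- pde_estimate(nit, n_grid = config$pde$n_grid,
                        quantile = config$pde$quantile,
                        subsample_cap = config$pde$subsample_cap)
  write_pde_curve(curve, art("pde_curve.csv"))

  ## stage 4: mixture fit + model selection
  mx <- config$mixture
  if (!is.null(mx$init)) {
    fit <- em_fit(nit, K = length(mx$init$weights), init = mx$init,
                  tol = mx$tol, max_iter = mx$max_iter)
    sel <- NULL
  } else {
    sel <- select_k(nit, mx$k_min, mx$k_max, mx$criterion, tol = mx$tol,
                    max_iter = mx$max_iter, n_restarts = mx$n_restarts,
                    seed = sub_seed(config$seed, 4L))
    fit <- sel$fits[[paste0("K", sel$chosen_K)]]
  }
  if (!is.null(sel))
    utils::write.table(sel$table, art("model_selection.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  else
    utils::write.table(data.frame(K = fit$K, loglik = fit$loglik,
                                  n_params = 3 * fit$K - 1,
                                  AIC = aic_gmm(fit$loglik, fit$K),
                                  BIC = bic_gmm(fit$loglik, fit$K, fit$n)),
                       art("model_selection.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  write_gmm_fit(fit, art("model.json"), selection = sel)

  ## stage 5: classification
  asg <- classify(fit, nit)
  cls_df <- data.frame(timestamp = format(tab$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                       residual = nit)
  for (j in seq_len(asg$K))
    cls_df[[paste0("posterior_", asg$class_names[j])]] <- asg$posteriors[, j]
  cls_df$label <- ifelse(is.na(asg$labels), "", asg$class_names[asg$labels])
  utils::write.table(cls_df, art("classification.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")

  ## stage 6: goodness of fit
  gof <- goodness_of_fit(fit, nit)
  jsonlite::write_json(list(chi2_stat = gof$chi2_stat, chi2_df = gof$chi2_df,
                            chi2_p = gof$chi2_p, ks_stat = gof$ks_stat,
                            ks_p = gof$ks_p, n = gof$n, n_bins = gof$n_bins,
                            fitted_model_caveat = gof$fitted_model_caveat,
                            qq_pairs = gof$qq_pairs),
                       art("gof.json"), auto_unbox = TRUE, digits = NA)

  ## stage 7: mode-conditioned comparison
  covars <- setdiff(names(tab$data), config$nitrate_var)
  groups <- lapply(stats::setNames(covars, covars),
                   function(v) group_by_mode(asg, det, v))
  cmp <- build_comparison(groups, alpha = config$compare$alpha,
                          correction_scope = config$compare$scope)
  write_comparison(cmp, art("comparison.tsv"))
  summ <- class_summaries(groups, with_pde = FALSE)
  utils::write.table(summ$table, art("class_summaries.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)

  ## stage 8: manifest
  artifacts <- c("residuals.csv", "pde_curve.csv", "model_selection.csv",
                 "model.json", "classification.csv", "gof.json",
                 "comparison.tsv", "class_summaries.csv", "manifest.json")
  manifest <- list(
    package = "nitratemodes",
    version = as.character(utils::packageVersion("nitratemodes")),
    seed = config$seed,
    settings = list(
      nitrate_var = config$nitrate_var,
      cutoff_period_days = config$detrend$cutoff_period,
      zero_baseline_variables = config$detrend$zero_baseline_variables,
      pde_quantile = config$pde$quantile,
      pde_subsample_cap = config$pde$subsample_cap,
      k_range = c(config$mixture$k_min, config$mixture$k_max),
      criterion = config$mixture$criterion,
      alpha = config$compare$alpha,
      correction_scope = config$compare$scope),
    chosen_K = fit$K,
    artifacts = artifacts)
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, table = tab, detrended = det,
                 pde = curve, selection = sel, fit = fit, assignment = asg,
                 gof = gof, comparison = cmp, summaries = summ))
}
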