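#' Simulate an element and write it to disk
#'
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param config A [sim_config()].
#' @param out_prefix Output path prefix.
#' @param seed Seed for the replicate.
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(phylogeny, model, config = sim_config(),
                         out_prefix = "element", seed = 1) {
  set.seed(seed)
  rep <- sim_study_replicate(phylogeny, model, config)
  paths <- write_replicate(rep, out_prefix)
  message("simulated element written to ", out_prefix, ".* (seed ", seed, ")")
  invisible(paths)
}

#' Fit the model to an element on disk
#'
#' Loads the alignment and trait table, runs the chains, writes one
#' tab-separated trace file per chain and a JSON summary.
#'
#' @param fasta,trait Input paths (FASTA alignment; two-column TSV).
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param config A [run_config()].
#' @param out_prefix Output path prefix; writes
#'   `<prefix>.chain<i>.tsv` and `<prefix>.summary.json`.
#' @param element_id Identifier recorded in the summary.
#' @return The `element_summary`, invisibly.
#' @export
cmd_fit <- function(fasta, trait, phylogeny, model, config = run_config(),
                    out_prefix = "fit", element_id = basename(out_prefix)) {
  set.seed(config$seed)
  element <- load_element(fasta, trait, phylogeny, model)
  summ <- fit_element(element, phylogeny, model, config,
                      element_id = element_id)
  for (i in seq_along(summ$run$traces)) {
    tr <- as.data.frame(summ$run$traces[[i]])
    tr <- cbind(iteration = seq_len(nrow(tr)) * config$thin, tr)
    utils::write.table(tr, paste0(out_prefix, ".chain", i, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sc <- summ$run$summary
  out <- list(element_id = summ$element_id, bf = summ$bf,
              label = categorize_evidence(summ$bf),
              median_log_beta_ratio = summ$median_log_beta_ratio,
              ci80 = summ$ci80,
              scalar_summary = stats::setNames(
                lapply(rownames(sc), function(r) as.list(sc[r, ])),
                rownames(sc)),
              rhat = as.list(summ$run$rhat),
              rhat_max = summ$rhat_max, converged = summ$converged,
              n_samples = summ$n_samples,
              acceptance = as.list(summ$run$acceptance),
              seed = config$seed)
  jsonlite::write_json(out, paste0(out_prefix, ".summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summ)
}

#' Simulation study: simulate, fit, and aggregate
#'
#' Reproduces the calibration and false-positive-rate experiments at a
#' chosen scale. Scenarios: `"prior"` draws every replicate's parameters
#' from the prior and measures recovery of `log(beta3/beta2)`;
#' `"neutral"`, `"conserved"` and `"barely_conserved"` fix
#' `beta2 = beta3 = 1` and apply one uniform rate multiplier (1, 0.2, 0.5)
#' to every branch, measuring the false-positive rate as a function of the
#' Bayes-factor cutoff. The FPR is computed among replicates passing the
#' convergence screen; non-converged replicates are tallied separately.
#'
#' @param phylogeny A `phylogeny`.
#' @param model A `neutral_model`.
#' @param scenario One of `"prior"`, `"neutral"`, `"conserved"`,
#'   `"barely_conserved"`.
#' @param n_reps Number of replicates.
#' @param S Element length in sites.
#' @param config A [run_config()]; per-replicate seeds are derived from
#'   `config$seed`.
#' @param fixed_trait Optional named leaf trait vector used instead of
#'   simulating the trait (the mammal-tree false-positive scenarios).
#' @param bf_cutoffs Cutoffs at which the FPR is tabulated.
#' @param verbose Print one line per replicate.
#' @return A `study_result`: list with `scenario`, `per_rep` (data frame),
#'   and `aggregates` (list with `mse`, `coverage80`, `fpr` table,
#'   `n_converged`, `n_reps`).
#' @export
run_study <- function(phylogeny, model, scenario = c("prior", "neutral",
                                                     "conserved",
                                                     "barely_conserved"),
                      n_reps = 30, S = 80, config = run_config(),
                      fixed_trait = NULL, bf_cutoffs = 1:10,
                      verbose = FALSE) {
  scenario <- match.arg(scenario)
  rate <- switch(scenario, prior = NULL, neutral = 1, conserved = 0.2,
                 barely_conserved = 0.5)
  scfg <- sim_config(S = S, neutral_override = rate,
                     fixed_trait = fixed_trait)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- as.integer((as.numeric(config$seed) * 48271 + i * 16807) %%
                             2147483399)
    set.seed(rep_seed)
    rep <- sim_study_replicate(phylogeny, model, scfg)
    element <- load_element(rep$alignment, data.frame(
      species = names(rep$trait), value = unname(rep$trait)),
      phylogeny, model)
    fit <- fit_element(element, phylogeny, model,
                       utils::modifyList(config, list(seed = rep_seed)),
                       element_id = sprintf("rep%04d", i))
    truth <- log(rep$params$beta3) - log(rep$params$beta2)
    rows[[i]] <- data.frame(
      rep = i, seed = rep_seed, true_log_beta_ratio = truth,
      median = fit$median_log_beta_ratio,
      ci80_lo = fit$ci80[1], ci80_hi = fit$ci80[2], bf = fit$bf,
      rhat_max = fit$rhat_max, converged = fit$converged)
    if (verbose)
      message(sprintf("rep %d/%d: truth %.3f median %.3f BF %.2f%s",
                      i, n_reps, truth, fit$median_log_beta_ratio, fit$bf,
                      if (fit$converged) "" else " [not converged]"))
  }
  per_rep <- do.call(rbind, rows)
  conv <- per_rep[per_rep$converged, , drop = FALSE]
  agg <- list(n_reps = n_reps, n_converged = nrow(conv))
  if (scenario == "prior") {
    # calibration aggregates use every replicate (the screen applies to
    # ranking and FPR, not to the recovery study)
    agg$mse <- mean((per_rep$median - per_rep$true_log_beta_ratio)^2)
    agg$coverage80 <- mean(per_rep$ci80_lo <= per_rep$true_log_beta_ratio &
                           per_rep$true_log_beta_ratio <= per_rep$ci80_hi)
  } else {
    agg$fpr <- data.frame(
      bf_cutoff = bf_cutoffs,
      fpr = vapply(bf_cutoffs, function(ct) mean(conv$bf >= ct), 0))
  }
  structure(list(scenario = scenario, per_rep = per_rep, aggregates = agg),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result (", x$scenario, "): ", x$aggregates$n_converged, "/",
      x$aggregates$n_reps, " replicates converged\n", sep = "")
  if (x$scenario == "prior") {
    cat("  MSE of median log(beta3/beta2):", format(x$aggregates$mse, digits = 3),
        "\n  80% CI coverage:", format(x$aggregates$coverage80, digits = 3), "\n")
  } else {
    print(x$aggregates$fpr, row.names = FALSE)
  }
  invisible(x)
}

#' Run a study and write its tables
#'
#' @inheritParams run_study
#' @param out_prefix Output prefix; writes `<prefix>.reps.tsv` and
#'   `<prefix>.aggregates.json`.
#' @return The `study_result`, invisibly.
#' @export
cmd_study <- function(phylogeny, model, scenario = "prior", n_reps = 30,
                      S = 80, config = run_config(), fixed_trait = NULL,
                      out_prefix = "study", verbose = TRUE) {
  res <- run_study(phylogeny, model, scenario, n_reps, S, config,
                   fixed_trait, verbose = verbose)
  utils::write.table(res$per_rep, paste0(out_prefix, ".reps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$aggregates, paste0(out_prefix, ".aggregates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(res)
}
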