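#' Cohort-level model comparison by out-of-sample log-likelihood
#'
#' Summarizes, for each candidate model, the out-of-sample log-likelihood of
#' the transfer-phase choices (mean, SD, median over subjects). The winning
#' model is the one with the highest mean; no complexity penalty is applied
#' because the evaluation is already out of sample.
#'
#' @param fits a `bandit_fits` data frame from [fit_cohort()] (every subject
#'   fitted under every model).
#' @return a data frame of class `comparison_table`: `model_id`,
#'   `n_subjects`, `mean_oos`, `sd_oos`, `median_oos`, with the winning
#'   model id in attribute `"winner"`.
#' @export
compare_models <- function(fits) {
  tab <- table(fits$subject_id, fits$model_id)
  if (any(tab != 1)) {
    gaps <- which(tab == 0, arr.ind = TRUE)
    stop("missing fits for subject x model: ",
         paste(rownames(tab)[gaps[, 1]], colnames(tab)[gaps[, 2]],
               sep = "/", collapse = ", "))
  }
  models <- unique(fits$model_id)
  out <- do.call(rbind, lapply(models, function(m) {
    x <- fits$oos_loglik[fits$model_id == m]
    data.frame(model_id = m, n_subjects = length(x), mean_oos = mean(x),
               sd_oos = stats::sd(x), median_oos = median(x),
               stringsAsFactors = FALSE)
  }))
  attr(out, "winner") <- out$model_id[which.max(out$mean_oos)]
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Out-of-sample log-likelihood by model (mean +/- SD, median):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %8.2f +/- %6.2f   median %8.2f   (n = %d)\n",
                x$model_id[i], x$mean_oos[i], x$sd_oos[i], x$median_oos[i],
                x$n_subjects[i]))
  cat("winner:", attr(x, "winner"), "\n")
  invisible(x)
}

fits_to_params <- function(row) {
  spec <- model_spec(row$model_id)
  args <- list(model_id = row$model_id, alpha_c = row$alpha_c,
               alpha_u = row$alpha_u, beta = row$beta)
  if (spec$model_id == "RANGE_W") args$omega <- row$omega
  if (spec$model_id == "RANGE_WPLUS") {
    args$omega_c <- row$omega_c; args$omega_u <- row$omega_u
  }
  do.call(agent_parameters, args)
}

#' Ex post simulation from fitted parameters
#'
#' Re-simulates the learning and transfer phases (fresh outcome draws) for
#' every fitted subject using that subject's fitted parameters, and
#' aggregates per-option transfer choice rates: replicate means within
#' subject, then subject means, then the cohort mean.
#'
#' @param fits a `bandit_fits` data frame restricted to one model (or pass
#'   `model` to select it).
#' @param design the [bandit_design()] to simulate on.
#' @param n_reps simulation replicates per subject; `0` returns an empty
#'   result.
#' @param seed integer master seed.
#' @param model model id to select from `fits` when it holds several.
#' @param rule transfer decision rule, `"argmax"` (default) or `"softmax"`.
#' @return a data frame `option_id`, `choice_rate` (cohort mean), with the
#'   subjects x options matrix of subject means in attribute
#'   `"subject_rates"`.
#' @export
ex_post_simulate <- function(fits, design, n_reps = 1L, seed = 1L,
                             model = unique(fits$model_id), rule = "argmax") {
  if (length(model) != 1)
    stop("fits contain several models; pass `model` to select one")
  fits <- fits[fits$model_id == model, , drop = FALSE]
  if (n_reps == 0 || nrow(fits) == 0)
    return(data.frame(option_id = character(0), choice_rate = numeric(0)))
  option_ids <- design$options$option_id
  seeds <- derive_seeds(seed, nrow(fits) * n_reps)
  subj_rates <- matrix(NA_real_, nrow(fits), length(option_ids),
                       dimnames = list(fits$subject_id, option_ids))
  k <- 0L
  for (i in seq_len(nrow(fits))) {
    params <- fits_to_params(fits[i, ])
    reps <- matrix(NA_real_, n_reps, length(option_ids))
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      sim <- simulate_agent(design, model, params, seeds[k], rule = rule,
                            subject_id = fits$subject_id[i])
      tcr <- transfer_choice_rate(sim$trials)
      reps[r, ] <- tcr$choice_rate[match(option_ids, tcr$option_id)]
    }
    subj_rates[i, ] <- colMeans(reps)
  }
  out <- data.frame(option_id = option_ids,
                    choice_rate = unname(colMeans(subj_rates)),
                    stringsAsFactors = FALSE)
  attr(out, "subject_rates") <- subj_rates
  out
}

#' Parameter recovery for one model
#'
#' Simulates agents with prior-drawn parameters, refits the generating model
#' to each agent's choices, and tabulates true against recovered parameters.
#'
#' @param model model id to simulate and refit.
#' @param design a [bandit_design()].
#' @param n_agents number of simulated agents (>= 2).
#' @param priors an [agent_priors()] object.
#' @param seed integer master seed.
#' @param n_restarts optimizer restarts per fit.
#' @return an object of class `recovery_report`: `pairs` (subject,
#'   parameter, true, recovered) and `summary` (parameter, Spearman rank
#'   correlation, median bias recovered - true).
#' @export
parameter_recovery <- function(model, design, n_agents, priors = agent_priors(),
                               seed = 1L, n_restarts = 20L) {
  stopifnot(n_agents >= 2)
  seeds <- derive_seeds(seed, 2L)
  coh <- simulate_cohort(model, design, n_agents, priors, seed = seeds[1])
  fits <- fit_cohort(coh$trials, models = model, n_restarts = n_restarts,
                     seed = seeds[2], priors = priors)
  par_names <- model_spec(model)$par_names
  pairs <- do.call(rbind, lapply(par_names, function(pn) {
    data.frame(subject_id = coh$parameters$subject_id, parameter = pn,
               true = coh$parameters[[pn]],
               recovered = fits[[pn]][match(coh$parameters$subject_id,
                                            fits$subject_id)],
               stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(par_names, function(pn) {
    x <- pairs[pairs$parameter == pn, ]
    data.frame(parameter = pn,
               spearman = suppressWarnings(
                 cor(x$true, x$recovered, method = "spearman")),
               median_bias = median(x$recovered - x$true),
               stringsAsFactors = FALSE)
  }))
  structure(list(model_id = model, pairs = pairs, summary = summary,
                 n_agents = n_agents),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %s model, %d agents\n", x$model_id,
              x$n_agents))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-8s rank correlation %.3f, median bias %+.3f\n",
                x$summary$parameter[i], x$summary$spearman[i],
                x$summary$median_bias[i]))
  invisible(x)
}

#' Model recovery (confusion matrix)
#'
#' Simulates cohorts under each generating model, fits every candidate model
#' to every simulated subject, and reports how often each candidate wins
#' (highest out-of-sample log-likelihood). A well-identified design shows a
#' dominant diagonal.
#'
#' @param models character vector of candidate (and generating) model ids.
#' @param design a [bandit_design()].
#' @param n_agents_per_model agents simulated per generating model.
#' @param priors an [agent_priors()] object.
#' @param seed integer master seed.
#' @param n_restarts optimizer restarts per fit.
#' @return an object of class `model_recovery`: `confusion` (rows =
#'   generating model, columns = best-fitting model, rows sum to 1) and
#'   `mean_oos` (cohort-mean out-of-sample log-likelihood per generating x
#'   candidate model).
#' @export
model_recovery <- function(models, design, n_agents_per_model,
                           priors = agent_priors(), seed = 1L,
                           n_restarts = 20L) {
  seeds <- derive_seeds(seed, 2L * length(models))
  confusion <- matrix(0, length(models), length(models),
                      dimnames = list(generator = models, best_fit = models))
  mean_oos <- confusion
  for (g in seq_along(models)) {
    coh <- simulate_cohort(models[g], design, n_agents_per_model, priors,
                           seed = seeds[g])
    fits <- fit_cohort(coh$trials, models = models, n_restarts = n_restarts,
                       seed = seeds[length(models) + g], priors = priors)
    for (s in unique(fits$subject_id)) {
      sub <- fits[fits$subject_id == s, ]
      best <- sub$model_id[which.max(sub$oos_loglik)]
      confusion[g, best] <- confusion[g, best] + 1
    }
    confusion[g, ] <- confusion[g, ] / n_agents_per_model
    for (m in seq_along(models))
      mean_oos[g, m] <-
        mean(fits$oos_loglik[fits$model_id == models[m]])
  }
  structure(list(confusion = confusion, mean_oos = mean_oos,
                 n_agents_per_model = n_agents_per_model),
            class = "model_recovery")
}

#' @export
print.model_recovery <- function(x, ...) {
  cat(sprintf("Model recovery (%d agents per generating model)\n",
              x$n_agents_per_model))
  cat("Best-fit frequencies (rows = generating model):\n")
  print(round(x$confusion, 3))
  cat("Cohort-mean out-of-sample log-likelihood:\n")
  print(round(x$mean_oos, 2))
  invisible(x)
}
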