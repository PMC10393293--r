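# --- trial encoding for the compiled replay ------------------------------

encode_learning <- function(trials, option_ids) {
  trials <- trials[trials$phase == "learning", , drop = FALSE]
  trials <- trials[order(trials$trial_index), , drop = FALSE]
  n <- nrow(trials)
  opt <- matrix(0L, n, 3)
  avail <- matrix(0L, n, 3)
  outcome <- matrix(NA_real_, n, 3)
  for (j in 1:3) {
    ids <- trials[[paste0("option", j)]]
    opt[, j] <- ifelse(is.na(ids), 0L, match(ids, option_ids))
    if (anyNA(opt[!is.na(ids), j]))
      stop("trial options not covered by option_ids")
    avail[, j] <- ifelse(is.na(ids), 0L,
                         as.integer(trials[[paste0("available", j)]]))
    outcome[, j] <- trials[[paste0("outcome", j)]]
  }
  forced <- as.integer(trials$forced)
  free_missing <- which(!trials$forced & is.na(trials$choice))
  if (length(free_missing))
    stop("free learning trial(s) without a recorded choice: trial_index ",
         paste(trials$trial_index[free_missing], collapse = ", "))
  choice <- integer(n)
  for (t in seq_len(n)) {
    slot <- match(trials$choice[t], c(trials$option1[t], trials$option2[t],
                                      trials$option3[t]))
    if (is.na(slot))
      stop("choice not among presented options at trial_index ",
           trials$trial_index[t])
    choice[t] <- slot
  }
  list(opt = opt, avail = avail, choice = choice, forced = forced,
       outcome = outcome, n_trials = n,
       n_free = sum(forced == 0L & rowSums(avail) >= 2))
}

trial_option_ids <- function(trials) {
  ids <- unique(c(trials$option1, trials$option2, trials$option3))
  sort(ids[!is.na(ids)])
}

replay_learning <- function(params, model, enc, option_ids) {
  spec <- as_model_spec(model)
  res <- replay_learning_cpp(par_vector(params), spec$code, enc$opt,
                             enc$avail, enc$choice, enc$forced, enc$outcome,
                             length(option_ids))
  list(nll = res$nll, q = setNames(res$q, option_ids),
       last_seen = setNames(res$last_seen, option_ids))
}

#' Learning-phase negative log-likelihood
#'
#' Replays a subject's learning phase deterministically under a model and
#' parameter set: the recorded choices and displayed outcomes drive the
#' delta-rule updates (nothing is resampled), and each free choice
#' contributes the log softmax probability of the option actually taken,
#' over the options selectable on that trial. Forced trials update values
#' but contribute no likelihood term.
#'
#' @param params an [agent_parameters()] object.
#' @param model a [model_spec()] or model id (must match `params`).
#' @param trials a subject's trial records; only `phase == "learning"` rows
#'   are used, in `trial_index` order.
#' @return the negative log-likelihood (a non-negative number).
#' @examples
#' coh <- simulate_cohort("RANGE", bandit_design("1a"), 1, seed = 1)
#' p <- agent_parameters("RANGE", 0.5, 0.5, 0)   # beta = 0: uniform policy
#' learning_negloglik(p, "RANGE", coh$trials)    # 180 * log(2)
#' @export
learning_negloglik <- function(params, model, trials) {
  option_ids <- trial_option_ids(trials[trials$phase == "learning", ])
  enc <- encode_learning(trials, option_ids)
  replay_learning(params, model, enc, option_ids)$nll
}

#' Out-of-sample log-likelihood of transfer-phase choices
#'
#' Sums the log softmax probability (at the fitted inverse temperature) of
#' each observed transfer choice given the final learned values of the two
#' cues on screen. Values are not updated during the transfer phase, which
#' delivers no feedback.
#'
#' @param fit a [fit_bandit()] result, or a named list with elements
#'   `final_q` (named value vector) and `par` containing `beta`.
#' @param transfer_trials transfer-phase trial records; defaults to the
#'   transfer trials stored in `fit`.
#' @return the summed log-likelihood (<= 0); 0 for an empty transfer set.
#' @export
transfer_oos_loglik <- function(fit, transfer_trials = fit$transfer) {
  if (is.null(transfer_trials) || nrow(transfer_trials) == 0) return(0)
  tr <- transfer_trials[transfer_trials$phase == "transfer", , drop = FALSE]
  if (nrow(tr) == 0) return(0)
  q <- fit$final_q
  beta <- fit$par[["beta"]]
  missing <- setdiff(unique(c(tr$option1, tr$option2)), names(q))
  if (length(missing))
    stop("no final value for cue(s): ", paste(missing, collapse = ", "))
  qa <- q[tr$option1]; qb <- q[tr$option2]
  q_ch <- ifelse(tr$choice == tr$option1, qa, qb)
  mx <- pmax(qa, qb) * beta
  sum(beta * q_ch - mx - log(exp(beta * qa - mx) + exp(beta * qb - mx)))
}

# transformed <-> natural parameter scales for bounded optimization
par_bounds <- function(spec) {
  k <- length(spec$par_names)
  lower <- c(-10, -10, -5, rep(-3, k - 3))
  upper <- c(10, 10, 5, rep(3, k - 3))
  list(lower = lower, upper = upper)
}

to_natural <- function(theta, spec) {
  p <- list(alpha_c = stats::plogis(theta[1]),
            alpha_u = stats::plogis(theta[2]), beta = exp(theta[3]))
  if (spec$model_id == "RANGE_W") p$omega <- exp(theta[4])
  if (spec$model_id == "RANGE_WPLUS") {
    p$omega_c <- exp(theta[4]); p$omega_u <- exp(theta[5])
  }
  do.call(agent_parameters, c(list(model_id = spec$model_id), p))
}

to_theta <- function(params, spec) {
  th <- c(stats::qlogis(params$alpha_c), stats::qlogis(params$alpha_u),
          log(params$beta))
  if (spec$model_id == "RANGE_W") th <- c(th, log(params$omega))
  if (spec$model_id == "RANGE_WPLUS")
    th <- c(th, log(params$omega_c), log(params$omega_u))
  th
}

#' Fit a normalization model to one subject's choices by maximum likelihood
#'
#' Estimates the model's free parameters (learning rates, inverse
#' temperature, and weighting exponent(s) where applicable) by minimizing
#' the learning-phase negative log-likelihood with bounded multi-start
#' quasi-Newton optimization (L-BFGS-B on logit/log-transformed
#' coordinates; the first start is the prior means, the rest are prior
#' draws). The fitted parameters are then evaluated out of sample: the
#' log-likelihood of the transfer-phase choices, which never enter the fit,
#' is computed from the final learned values and the fitted inverse
#' temperature.
#'
#' @param trials one subject's trial records (learning and, optionally,
#'   transfer phase rows).
#' @param model a [model_spec()] or model id.
#' @param n_restarts number of optimizer restarts (default 20).
#' @param seed integer seed for the restart draws (deterministic refits).
#' @param priors an [agent_priors()] object used for restart points.
#' @param control passed to [stats::optim()] (method `"L-BFGS-B"`).
#' @return an object of class `bandit_fit` with elements `model_id`, `par`
#'   (named, natural scale), `learning_loglik`, `final_q`, `oos_loglik`,
#'   `n_restarts_used`, `converged`, `n_free_choices`, plus the stored
#'   learning/transfer records. Methods: [print()], [summary()], [coef()],
#'   [logLik()], [predict()], [residuals()], [simulate()], [plot()].
#' @examples
#' coh <- simulate_cohort("RANGE", bandit_design("1a"), 1, seed = 1)
#' fit <- fit_bandit(coh$trials, "RANGE", n_restarts = 2, seed = 1)
#' coef(fit)
#' @export
fit_bandit <- function(trials, model, n_restarts = 20L, seed = 1L,
                       priors = agent_priors(), control = list()) {
  spec <- as_model_spec(model)
  learning <- trials[trials$phase == "learning", , drop = FALSE]
  transfer <- trials[trials$phase == "transfer", , drop = FALSE]
  if (nrow(learning) == 0) stop("no learning-phase trials to fit")
  option_ids <- trial_option_ids(trials)
  enc <- encode_learning(learning, option_ids)
  if (enc$n_free < 1) stop("no free-choice learning trials to fit")
  b <- par_bounds(spec)

  objective <- function(theta) {
    replay_learning(to_natural(theta, spec), spec, enc, option_ids)$nll
  }

  starts <- vector("list", n_restarts)
  starts[[1]] <- to_theta(
    do.call(agent_parameters,
            c(list(model_id = spec$model_id, alpha_c = 0.5, alpha_u = 0.5,
                   beta = priors$beta_shape * priors$beta_scale),
              if (spec$model_id == "RANGE_W") list(omega = 1),
              if (spec$model_id == "RANGE_WPLUS")
                list(omega_c = 1, omega_u = 1))),
    spec)
  if (n_restarts > 1) {
    draws <- with_seed(seed, lapply(seq_len(n_restarts - 1), function(i)
      sample_agent_parameters(spec, priors)))
    for (i in seq_along(draws))
      starts[[i + 1]] <- pmin(pmax(to_theta(draws[[i]], spec), b$lower),
                              b$upper)
  }

  best <- NULL
  n_ok <- 0L
  for (st in starts) {
    res <- tryCatch(
      optim(st, objective, method = "L-BFGS-B", lower = b$lower,
            upper = b$upper, control = control),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(model_id = spec$model_id, par = NULL,
                          learning_loglik = NA_real_, final_q = NULL,
                          oos_loglik = NA_real_,
                          n_restarts_used = n_restarts, converged = FALSE,
                          n_free_choices = enc$n_free, learning = learning,
                          transfer = transfer),
                     class = "bandit_fit"))

  params <- to_natural(best$par, spec)
  rep_final <- replay_learning(params, spec, enc, option_ids)
  fit <- structure(
    list(model_id = spec$model_id,
         par = setNames(unlist(params[spec$par_names]), spec$par_names),
         params = params,
         learning_loglik = -rep_final$nll,
         final_q = rep_final$q,
         oos_loglik = NA_real_,
         n_restarts_used = n_restarts,
         converged = n_ok > 0L && best$convergence == 0L,
         n_free_choices = enc$n_free,
         subject_id = if (nrow(learning)) learning$subject_id[1] else NA,
         experiment_id = if (nrow(learning)) learning$experiment_id[1] else NA,
         learning = learning, transfer = transfer),
    class = "bandit_fit")
  fit$oos_loglik <- transfer_oos_loglik(fit)
  fit
}

#' @export
print.bandit_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit: %s model, subject %s\n", x$model_id,
              x$subject_id))
  if (is.null(x$par)) {
    cat("  optimization failed on every restart (non-converged)\n")
    return(invisible(x))
  }
  cat("  parameters:",
      paste(sprintf("%s = %.3f", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  learning log-likelihood: %.2f (%d free choices)\n",
              x$learning_loglik, x$n_free_choices))
  if (nrow(x$transfer))
    cat(sprintf("  out-of-sample transfer log-likelihood: %.2f (%d trials)\n",
                x$oos_loglik, nrow(x$transfer)))
  invisible(x)
}

#' @export
coef.bandit_fit <- function(object, ...) object$par

#' @export
logLik.bandit_fit <- function(object, ...) {
  structure(object$learning_loglik, df = length(object$par),
            nobs = object$n_free_choices, class = "logLik")
}

#' @export
summary.bandit_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.bandit_fit")
}

#' @export
print.summary.bandit_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$final_q)) {
    cat("  final learned values:\n")
    q <- x$fit$final_q
    for (i in seq_along(q))
      cat(sprintf("    %-6s %.3f\n", names(q)[i], q[i]))
  }
  invisible(x)
}

#' Predicted choice probabilities from a fitted model
#'
#' For `phase = "learning"`, replays the learning phase at the fitted
#' parameters and returns, for each free trial, the softmax probability of
#' the choice the subject actually made. For `phase = "transfer"`, returns
#' the probability of each observed transfer choice from the final learned
#' values and fitted inverse temperature.
#'
#' @param object a `bandit_fit`.
#' @param phase `"transfer"` (default) or `"learning"`.
#' @param ... unused.
#' @return numeric vector of probabilities, one per (free) trial.
#' @export
predict.bandit_fit <- function(object, phase = c("transfer", "learning"),
                               ...) {
  phase <- match.arg(phase)
  if (is.null(object$par)) stop("non-converged fit has no parameters")
  if (phase == "transfer") {
    tr <- object$transfer
    if (nrow(tr) == 0) return(numeric(0))
    q <- object$final_q; beta <- object$par[["beta"]]
    qa <- q[tr$option1]; qb <- q[tr$option2]
    q_ch <- ifelse(tr$choice == tr$option1, qa, qb)
    mx <- pmax(qa, qb) * beta
    return(unname(exp(beta * q_ch - mx) /
                    (exp(beta * qa - mx) + exp(beta * qb - mx))))
  }
  replay_choice_probs(object$params, object$model_id, object$learning)
}

# pure-R replay built from the exported primitives; returns P(observed
# choice) for each free learning trial
replay_choice_probs <- function(params, model, learning) {
  spec <- as_model_spec(model)
  learning <- learning[order(learning$trial_index), , drop = FALSE]
  state <- value_state(spec, trial_option_ids(learning))
  probs <- numeric(0)
  for (t in seq_len(nrow(learning))) {
    row <- learning[t, ]
    so <- schedule_options(row)
    chosen <- match(row$choice, so$ids)
    if (!row$forced && sum(so$avail) >= 2) {
      p <- softmax_probabilities(state$q[so$ids], params$beta, so$avail)
      probs <- c(probs, p[chosen])
    }
    shown <- unlist(row[paste0("outcome", seq_along(so$ids))],
                    use.names = FALSE)
    rf <- resolve_feedback(state, so$ids, shown)
    state <- rf$state
    u <- subjective_outcomes(spec, rf$outcomes, chosen, params)
    state <- update_values(state, so$ids, u, chosen, params)
  }
  probs
}

#' @export
residuals.bandit_fit <- function(object, phase = c("transfer", "learning"),
                                 ...) {
  1 - predict(object, phase = match.arg(phase))
}

#' Ex post re-simulation of a fitted subject
#'
#' Re-simulates the full task (fresh outcome draws) with the fitted
#' parameters, mirroring the generative check in which fitted models must
#' reproduce the behavioral pattern they were estimated on.
#'
#' @param object a `bandit_fit`.
#' @param nsim number of replicate simulations.
#' @param seed integer seed.
#' @param rule transfer decision rule, `"argmax"` (default) or `"softmax"`.
#' @param design the task design; defaults to the built-in design named by
#'   the fitted records' `experiment_id`.
#' @param ... unused.
#' @return a list of `nsim` trial-record data frames.
#' @export
simulate.bandit_fit <- function(object, nsim = 1, seed = 1L,
                                rule = "argmax",
                                design = bandit_design(object$experiment_id),
                                ...) {
  if (is.null(object$par)) stop("non-converged fit has no parameters")
  seeds <- derive_seeds(seed, nsim)
  lapply(seq_len(nsim), function(i)
    simulate_agent(design, object$model_id, object$params, seeds[i],
                   rule = rule,
                   subject_id = paste0(object$subject_id, "_sim", i))$trials)
}

#' @export
plot.bandit_fit <- function(x, seed = 1L, ...) {
  obs <- transfer_choice_rate(x$transfer)
  sim <- transfer_choice_rate(simulate(x, nsim = 1, seed = seed)[[1]])
  ord <- order(obs$option_id)
  bp <- barplot(sim$choice_rate[match(obs$option_id[ord], sim$option_id)],
                names.arg = obs$option_id[ord], las = 2, ylim = c(0, 1),
                ylab = "transfer choice rate",
                main = paste(x$model_id, "fit: simulated (bars) vs observed"),
                ...)
  points(bp, obs$choice_rate[ord], pch = 19)
  invisible(x)
}

#' Fit several models to every subject of a cohort
#'
#' @param trials stacked trial records for one or more subjects.
#' @param models character vector of model ids to fit.
#' @param n_restarts,seed,priors,control passed to [fit_bandit()]; each
#'   subject x model fit gets its own deterministic sub-seed.
#' @return a data frame of class `bandit_fits`, one row per subject x model:
#'   fitted parameters, `learning_loglik`, `oos_loglik`, `converged`. The
#'   final learned values are attached as the `"final_q"` attribute (a list
#'   keyed by `subject_id.model_id`).
#' @export
fit_cohort <- function(trials, models = c("UNBIASED", "DIVISIVE", "RANGE"),
                       n_restarts = 20L, seed = 1L,
                       priors = agent_priors(), control = list()) {
  subjects <- unique(trials$subject_id)
  seeds <- derive_seeds(seed, length(subjects) * length(models))
  rows <- list()
  final_q <- list()
  k <- 0L
  for (s in subjects) {
    sub <- trials[trials$subject_id == s, , drop = FALSE]
    for (m in models) {
      k <- k + 1L
      fit <- fit_bandit(sub, m, n_restarts = n_restarts, seed = seeds[k],
                        priors = priors, control = control)
      p <- as.list(fit$par)
      rows[[k]] <- data.frame(
        subject_id = s, model_id = m,
        alpha_c = p$alpha_c %||% NA_real_,
        alpha_u = p$alpha_u %||% NA_real_,
        beta = p$beta %||% NA_real_,
        omega = p$omega %||% NA_real_,
        omega_c = p$omega_c %||% NA_real_,
        omega_u = p$omega_u %||% NA_real_,
        learning_loglik = fit$learning_loglik,
        oos_loglik = fit$oos_loglik,
        n_restarts_used = fit$n_restarts_used,
        converged = fit$converged, stringsAsFactors = FALSE)
      final_q[[paste(s, m, sep = ".")]] <- fit$final_q
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "final_q") <- final_q
  class(out) <- c("bandit_fits", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
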