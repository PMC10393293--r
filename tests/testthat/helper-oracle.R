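# Independent brute-force replay of the learning phase, written directly
# from the model equations (delta rule over subjectively encoded outcomes,
# softmax likelihood of free choices over the selectable set). Kept separate
# from the package implementation on purpose: tests compare the two paths.

oracle_negloglik <- function(p, model_id, trials, return_q = FALSE) {
  lt <- trials[trials$phase == "learning", , drop = FALSE]
  lt <- lt[order(lt$trial_index), , drop = FALSE]
  opts <- c(lt$option1, lt$option2, lt$option3)
  opts <- sort(unique(opts[!is.na(opts)]))
  q <- setNames(rep(if (model_id == "UNBIASED") 50 else 0.5, length(opts)),
                opts)
  seen <- setNames(rep(NA_real_, length(opts)), opts)
  nll <- 0
  for (i in seq_len(nrow(lt))) {
    ids <- c(lt$option1[i], lt$option2[i], lt$option3[i])
    keep <- !is.na(ids)
    ids <- ids[keep]
    av <- c(lt$available1[i], lt$available2[i], lt$available3[i])[keep]
    shown <- c(lt$outcome1[i], lt$outcome2[i], lt$outcome3[i])[keep]
    raw <- shown
    for (k in which(is.na(raw)))
      raw[k] <- if (is.na(seen[[ids[k]]])) 50 else seen[[ids[k]]]
    ch <- match(lt$choice[i], ids)
    if (!lt$forced[i] && sum(av) >= 2) {
      z <- p$beta * q[ids[av]]
      m <- max(z)
      nll <- nll - (p$beta * q[[ids[ch]]] - m - log(sum(exp(z - m))))
    }
    u <- switch(model_id,
      UNBIASED = raw,
      DIVISIVE = raw / sum(raw),
      {
        mn <- min(raw); mx <- max(raw)
        v <- if (mx == mn) rep(0.5, length(raw)) else (raw - mn) / (mx - mn)
        if (model_id == "RANGE_W") v <- v ^ p$omega
        if (model_id == "RANGE_WPLUS") {
          w <- rep(p$omega_u, length(v)); w[ch] <- p$omega_c
          v <- v ^ w
        }
        v
      })
    for (k in seq_along(ids)) {
      a <- if (k == ch) p$alpha_c else p$alpha_u
      q[[ids[k]]] <- q[[ids[k]]] + a * (u[k] - q[[ids[k]]])
    }
    for (k in which(!is.na(shown))) seen[[ids[k]]] <- shown[k]
  }
  if (return_q) list(nll = nll, q = q) else nll
}

oracle_params <- function(model_id, p) {
  do.call(agent_parameters, c(
    list(model_id = model_id, alpha_c = p$alpha_c, alpha_u = p$alpha_u,
         beta = p$beta),
    if (model_id == "RANGE_W") list(omega = p$omega),
    if (model_id == "RANGE_WPLUS")
      list(omega_c = p$omega_c, omega_u = p$omega_u)))
}

random_point <- function() {
  list(alpha_c = runif(1), alpha_u = runif(1), beta = runif(1, 0, 20),
       omega = exp(runif(1, -2, 2)), omega_c = exp(runif(1, -2, 2)),
       omega_u = exp(runif(1, -2, 2)))
}

# minimal hand-built trial records for unit tests
make_trials <- function(phase, option_sets, choices, outcomes = NULL,
                        available = NULL, forced = NULL, ratings = NULL,
                        subject_id = "t1", experiment_id = "toy") {
  n <- length(option_sets)
  df <- data.frame(subject_id = subject_id, experiment_id = experiment_id,
                   phase = phase, trial_index = seq_len(n),
                   context_id = NA_character_, option1 = NA_character_,
                   option2 = NA_character_, option3 = NA_character_,
                   available1 = NA, available2 = NA, available3 = NA,
                   forced = FALSE, choice = NA_character_,
                   outcome1 = NA_real_, outcome2 = NA_real_,
                   outcome3 = NA_real_, rating = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ids <- option_sets[[i]]
    df[i, paste0("option", seq_along(ids))] <- ids
    av <- if (is.null(available)) rep(TRUE, length(ids)) else available[[i]]
    df[i, paste0("available", seq_along(ids))] <- av
    if (!is.null(outcomes))
      df[i, paste0("outcome", seq_along(ids))] <- outcomes[[i]]
    if (!is.null(choices)) df$choice[i] <- choices[i]
    if (!is.null(forced)) df$forced[i] <- forced[i]
    if (!is.null(ratings)) df$rating[i] <- ratings[i]
    df$context_id[i] <- paste(ids, collapse = "+")
  }
  df
}

# design 1a reused across test files
design_1a <- bandit_design("1a")
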