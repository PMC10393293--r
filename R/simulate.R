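#' Priors over agent parameters
#'
#' Population distributions used both for ex ante simulation and as restart
#' points for fitting: learning rates ~ Beta(1.1, 1.1) (mean 0.5, near-flat),
#' inverse temperature ~ Gamma(shape 1.2, scale 5) (mean 6), and, for the
#' exponent models, omega ~ log-normal(0, 0.5) (median 1, the linear case).
#'
#' @param alpha_shape1,alpha_shape2 Beta shape parameters for learning rates.
#' @param beta_shape,beta_scale Gamma shape and scale for the inverse
#'   temperature (shape-scale parametrization).
#' @param omega_meanlog,omega_sdlog log-normal parameters for the weighting
#'   exponent(s).
#' @return an object of class `agent_priors`.
#' @export
agent_priors <- function(alpha_shape1 = 1.1, alpha_shape2 = 1.1,
                         beta_shape = 1.2, beta_scale = 5,
                         omega_meanlog = 0, omega_sdlog = 0.5) {
  structure(list(alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
                 beta_shape = beta_shape, beta_scale = beta_scale,
                 omega_meanlog = omega_meanlog, omega_sdlog = omega_sdlog),
            class = "agent_priors")
}

#' Draw one agent's parameters from the priors
#'
#' Draws are independent across parameters and use the current RNG stream;
#' wrap in `set.seed()` (or use [simulate_cohort()]) for reproducibility.
#'
#' @param model a [model_spec()] or model id.
#' @param priors an [agent_priors()] object.
#' @return an [agent_parameters()] object.
#' @export
sample_agent_parameters <- function(model, priors = agent_priors()) {
  spec <- as_model_spec(model)
  ac <- rbeta(1, priors$alpha_shape1, priors$alpha_shape2)
  au <- rbeta(1, priors$alpha_shape1, priors$alpha_shape2)
  b <- rgamma(1, shape = priors$beta_shape, scale = priors$beta_scale)
  if (spec$model_id == "RANGE_W") {
    agent_parameters(spec, ac, au, b,
                     omega = rlnorm(1, priors$omega_meanlog,
                                    priors$omega_sdlog))
  } else if (spec$model_id == "RANGE_WPLUS") {
    agent_parameters(spec, ac, au, b,
                     omega_c = rlnorm(1, priors$omega_meanlog,
                                      priors$omega_sdlog),
                     omega_u = rlnorm(1, priors$omega_meanlog,
                                      priors$omega_sdlog))
  } else {
    agent_parameters(spec, ac, au, b)
  }
}

schedule_options <- function(row) {
  ids <- unlist(row[paste0("option", 1:3)], use.names = FALSE)
  keep <- !is.na(ids)
  list(ids = ids[keep],
       avail = unlist(row[paste0("available", 1:3)],
                      use.names = FALSE)[keep])
}

empty_records <- function(n) {
  data.frame(subject_id = character(n), experiment_id = character(n),
             phase = character(n), trial_index = integer(n),
             context_id = NA_character_, option1 = NA_character_,
             option2 = NA_character_, option3 = NA_character_,
             available1 = NA, available2 = NA, available3 = NA,
             forced = FALSE, choice = NA_character_,
             outcome1 = NA_real_, outcome2 = NA_real_, outcome3 = NA_real_,
             rating = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate one agent through all three task phases
#'
#' Plays the learning phase trial by trial (outcomes sampled around the
#' design's means, free choices drawn from the softmax over selectable
#' options, forced choices executed as instructed, values updated by the
#' delta rule after feedback resolution), then the transfer phase from the
#' final learned values (argmax rule by default, ties resolved by a fair
#' coin; softmax optional), then the explicit phase, where ratings are the
#' final values mapped to the 0-100 scale plus truncated Gaussian noise.
#'
#' @param design a [bandit_design()].
#' @param model a [model_spec()] or model id.
#' @param params an [agent_parameters()] object.
#' @param seed integer seed governing every random draw for this agent.
#' @param rule transfer-phase decision rule, `"argmax"` or `"softmax"`.
#' @param rating_noise_sd SD (rating points) of explicit-rating noise.
#' @param subject_id identifier stamped on the trial records.
#' @return a list of class `simulated_subject`: `trials` (trial-record data
#'   frame over all phases), `final_state` (the [value_state()] after
#'   learning), `params`, `model_id`, `design`.
#' @examples
#' p <- agent_parameters("RANGE", 0.4, 0.2, 6)
#' s <- simulate_agent(bandit_design("1a"), "RANGE", p, seed = 1)
#' table(s$trials$phase)
#' @export
simulate_agent <- function(design, model, params, seed, rule = "argmax",
                           rating_noise_sd = 5, subject_id = "s1") {
  spec <- as_model_spec(model)
  rule <- match.arg(rule, c("argmax", "softmax"))
  seeds <- derive_seeds(seed, 4L)
  learn <- learning_schedule(design, seeds[1])
  trans <- transfer_schedule(design, seeds[2])
  expl <- explicit_schedule(design, seeds[3])
  means <- setNames(design$options$mean_outcome, design$options$option_id)
  sds <- setNames(
    rep(vapply(design$contexts, `[[`, 0, "outcome_sd"),
        times = vapply(design$contexts, function(ct) length(ct$means), 0L)),
    design$options$option_id)
  state <- value_state(spec, design$options$option_id)

  out <- with_seed(seeds[4], {
    rec <- empty_records(nrow(learn) + nrow(trans) + nrow(expl))
    rec$phase <- c(learn$phase, trans$phase, expl$phase)
    rec$trial_index <- c(learn$trial, trans$trial, expl$trial)
    rec$context_id <- c(learn$context_id, trans$context_id, expl$context_id)
    for (j in 1:3) {
      rec[[paste0("option", j)]] <-
        c(learn[[paste0("option", j)]], trans[[paste0("option", j)]],
          expl[[paste0("option", j)]])
      rec[[paste0("available", j)]] <-
        c(learn[[paste0("available", j)]], trans[[paste0("available", j)]],
          expl[[paste0("available", j)]])
    }
    rec$forced <- c(!is.na(learn$forced_option),
                    rep(FALSE, nrow(trans) + nrow(expl)))

    # learning phase
    for (t in seq_len(nrow(learn))) {
      row <- learn[t, ]
      so <- schedule_options(row)
      raw <- sample_outcome(means[so$ids], sds[so$ids], length(so$ids))
      if (!is.na(row$forced_option)) {
        chosen <- match(row$forced_option, so$ids)
      } else {
        p <- softmax_probabilities(state$q[so$ids], params$beta, so$avail)
        chosen <- sample.int(length(so$ids), 1L, prob = p)
      }
      observed <- if (identical(row$feedback, "partial")) {
        seq_along(so$ids) == chosen
      } else rep(TRUE, length(so$ids))
      shown <- ifelse(observed, raw, NA_real_)
      rf <- resolve_feedback(state, so$ids, shown)
      state <- rf$state
      u <- subjective_outcomes(spec, rf$outcomes, chosen, params)
      state <- update_values(state, so$ids, u, chosen, params)
      rec$choice[t] <- so$ids[chosen]
      rec[t, paste0("outcome", seq_along(so$ids))] <- shown
    }

    # transfer phase: no feedback, no updating
    off <- nrow(learn)
    for (t in seq_len(nrow(trans))) {
      a <- trans$option1[t]; b <- trans$option2[t]
      p_a <- if (rule == "argmax") {
        argmax_choice_probability(state$q[[a]], state$q[[b]])
      } else {
        softmax_probabilities(c(state$q[[a]], state$q[[b]]), params$beta)[1]
      }
      rec$choice[off + t] <- if (runif(1) < p_a) a else b
    }

    # explicit phase: final values mapped to the 0-100 rating scale
    off <- nrow(learn) + nrow(trans)
    scale <- if (spec$model_id == "UNBIASED") 1 else 100
    for (t in seq_len(nrow(expl))) {
      base <- scale * state$q[[expl$option1[t]]]
      rec$rating[off + t] <-
        min(max(base + rnorm(1, 0, rating_noise_sd), 0), 100)
    }
    rec
  })
  out$subject_id <- subject_id
  out$experiment_id <- design$experiment_id
  structure(list(trials = out, final_state = state, params = params,
                 model_id = spec$model_id, design = design),
            class = "simulated_subject")
}

#' Simulate a cohort of agents
#'
#' Draws `n_agents` independent parameter sets from the priors and simulates
#' each agent through all phases with its own schedule randomization; all
#' randomness derives from `seed` via per-subject substreams, so the same
#' seed reproduces the cohort bit for bit.
#'
#' @inheritParams simulate_agent
#' @param n_agents number of agents (the reference cohort size is 50).
#' @param priors an [agent_priors()] object.
#' @return a list of class `bandit_cohort`: `trials` (stacked trial records),
#'   `parameters` (one row per subject: true generating parameters),
#'   `final_q` (subjects x options matrix of final learned values),
#'   `model_id`, `design`.
#' @examples
#' coh <- simulate_cohort("RANGE", bandit_design("1a"), n_agents = 2, seed = 1)
#' nrow(coh$parameters)
#' @export
simulate_cohort <- function(model, design, n_agents, priors = agent_priors(),
                            seed = 1L, rule = "argmax",
                            rating_noise_sd = 5) {
  stopifnot(n_agents >= 1)
  spec <- as_model_spec(model)
  seeds <- derive_seeds(seed, 2L * n_agents)
  subjects <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    params <- with_seed(seeds[i], sample_agent_parameters(spec, priors))
    subjects[[i]] <- simulate_agent(design, spec, params,
                                    seed = seeds[n_agents + i], rule = rule,
                                    rating_noise_sd = rating_noise_sd,
                                    subject_id = sprintf("s%03d", i))
  }
  par_rows <- lapply(subjects, function(s) {
    p <- s$params
    data.frame(subject_id = s$trials$subject_id[1], model_id = s$model_id,
               alpha_c = p$alpha_c, alpha_u = p$alpha_u, beta = p$beta,
               omega = if (is.null(p$omega)) NA_real_ else p$omega,
               omega_c = if (is.null(p$omega_c)) NA_real_ else p$omega_c,
               omega_u = if (is.null(p$omega_u)) NA_real_ else p$omega_u,
               stringsAsFactors = FALSE)
  })
  final_q <- do.call(rbind, lapply(subjects, function(s) s$final_state$q))
  rownames(final_q) <- vapply(subjects, function(s) s$trials$subject_id[1], "")
  structure(list(trials = do.call(rbind, lapply(subjects, `[[`, "trials")),
                 parameters = do.call(rbind, par_rows),
                 final_q = final_q, model_id = spec$model_id,
                 design = design),
            class = "bandit_cohort")
}

#' @export
print.bandit_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d %s agents on design %s (%d trials)\n",
              nrow(x$parameters), x$model_id, x$design$experiment_id,
              nrow(x$trials)))
  invisible(x)
}

#' Transfer choices implied by explicit ratings
#'
#' Applies the greedy (argmax) rule to explicitly reported per-cue values:
#' for each cue pair the higher-rated cue is chosen with probability 1 (0.5
#' on a tie), and per-option choice rates are aggregated as in the transfer
#' phase (chosen count / presentation count).
#'
#' @param ratings named numeric vector, one rating per cue.
#' @param pairs two-column matrix of cue pairs; defaults to all pairs.
#' @return data frame with `option_id` and `choice_rate`.
#' @examples
#' simulate_choices_from_ratings(c(a = 10, b = 50, c = 90))
#' @export
simulate_choices_from_ratings <- function(ratings,
                                          pairs = transfer_pairs(names(ratings))) {
  pairs <- as.matrix(pairs)
  cues <- unique(c(pairs))
  missing <- setdiff(cues, names(ratings))
  if (length(missing))
    stop("missing rating for cue(s): ", paste(missing, collapse = ", "))
  chosen <- setNames(numeric(length(cues)), cues)
  shown <- setNames(numeric(length(cues)), cues)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    p_a <- argmax_choice_probability(ratings[[a]], ratings[[b]])
    chosen[a] <- chosen[a] + p_a
    chosen[b] <- chosen[b] + (1 - p_a)
    shown[a] <- shown[a] + 1
    shown[b] <- shown[b] + 1
  }
  data.frame(option_id = cues, choice_rate = unname(chosen / shown),
             stringsAsFactors = FALSE)
}
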