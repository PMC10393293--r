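#' Outcome-encoding model specification
#'
#' The five candidate models differ only in how a displayed raw outcome
#' (points) is converted into a subjective outcome before the delta-rule
#' update, and in the initial value `q_init`:
#' \describe{
#'   \item{UNBIASED}{subjective value = objective points; `q_init = 50`.}
#'   \item{DIVISIVE}{each outcome divided by the sum of the outcomes
#'     presented on the trial; `q_init = 0.5`.}
#'   \item{RANGE}{each outcome rescaled to its position between the trial's
#'     minimum and maximum outcome; `q_init = 0.5`.}
#'   \item{RANGE_W}{range-normalized outcome raised to a power `omega`.}
#'   \item{RANGE_WPLUS}{as RANGE_W, with separate exponents for the obtained
#'     (`omega_c`) and forgone (`omega_u`) outcomes.}
#' }
#'
#' @param model_id one of `"UNBIASED","DIVISIVE","RANGE","RANGE_W","RANGE_WPLUS"`.
#' @return an object of class `model_spec` with `model_id`, `q_init`,
#'   `par_names` and the internal integer `code`.
#' @examples
#' model_spec("RANGE")$q_init  # 0.5
#' @export
model_spec <- function(model_id) {
  if (length(model_id) != 1L || !model_id %in% MODEL_IDS)
    stop("unknown model id ", deparse(model_id), "; valid ids: ",
         paste(MODEL_IDS, collapse = ", "))
  par_names <- switch(model_id,
    RANGE_W = c("alpha_c", "alpha_u", "beta", "omega"),
    RANGE_WPLUS = c("alpha_c", "alpha_u", "beta", "omega_c", "omega_u"),
    c("alpha_c", "alpha_u", "beta"))
  structure(list(model_id = model_id,
                 q_init = if (model_id == "UNBIASED") 50 else 0.5,
                 par_names = par_names,
                 code = match(model_id, MODEL_IDS)),
            class = "model_spec")
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

#' Agent parameter set
#'
#' Validates and bundles the free parameters of one agent: learning rates for
#' the chosen (`alpha_c`) and unchosen (`alpha_u`) options, both in \[0,1\];
#' the softmax inverse temperature `beta > 0` (0 allowed as the random-choice
#' limit); and, for the nonlinear range models, the weighting exponent(s)
#' in (0, Inf).
#'
#' @param model_id model identifier, see [model_spec()].
#' @param alpha_c,alpha_u learning rates in \[0,1\].
#' @param beta inverse temperature, >= 0.
#' @param omega weighting exponent (RANGE_W only).
#' @param omega_c,omega_u chosen/unchosen weighting exponents (RANGE_WPLUS).
#' @return an object of class `agent_parameters`.
#' @examples
#' agent_parameters("RANGE", alpha_c = 0.3, alpha_u = 0.1, beta = 5)
#' @export
agent_parameters <- function(model_id, alpha_c, alpha_u, beta,
                             omega = NULL, omega_c = NULL, omega_u = NULL) {
  spec <- as_model_spec(model_id)
  chk <- function(x, nm, lo, hi, lo_open = FALSE) {
    if (is.null(x) || length(x) != 1L || is.na(x))
      stop("parameter ", nm, " is required for model ", spec$model_id)
    if (x > hi || x < lo || (lo_open && x == lo))
      stop("parameter ", nm, " = ", x, " outside its range")
    as.numeric(x)
  }
  p <- list(alpha_c = chk(alpha_c, "alpha_c", 0, 1),
            alpha_u = chk(alpha_u, "alpha_u", 0, 1),
            beta = chk(beta, "beta", 0, Inf))
  if (spec$model_id == "RANGE_W")
    p$omega <- chk(omega, "omega", 0, Inf, lo_open = TRUE)
  if (spec$model_id == "RANGE_WPLUS") {
    p$omega_c <- chk(omega_c, "omega_c", 0, Inf, lo_open = TRUE)
    p$omega_u <- chk(omega_u, "omega_u", 0, Inf, lo_open = TRUE)
  }
  structure(c(p, list(model_id = spec$model_id)),
            class = "agent_parameters")
}

# (alpha_c, alpha_u, beta, w_c, w_u) vector handed to the C++ replay
par_vector <- function(params) {
  w <- switch(params$model_id,
    RANGE_W = c(params$omega, params$omega),
    RANGE_WPLUS = c(params$omega_c, params$omega_u),
    c(1, 1))
  c(params$alpha_c, params$alpha_u, params$beta, w)
}

#' Subjective encoding of a trial's outcomes
#'
#' Applies the model's normalization rule to the raw outcome vector of one
#' trial. Contextual statistics (minimum, maximum, sum) are computed over
#' exactly the outcomes presented on that trial, including outcomes of
#' displayed-but-unavailable options.
#'
#' @param model a [model_spec()] or model id.
#' @param raw_outcomes numeric vector of 2 or 3 displayed outcomes (points).
#' @param chosen_index position of the obtained outcome (needed by
#'   RANGE_WPLUS, which weights obtained and forgone outcomes differently).
#' @param params an [agent_parameters()] object (needed for the exponent
#'   models; ignored otherwise).
#' @return numeric vector of subjective outcomes, same length as input.
#'   A degenerate trial (max = min) maps every outcome to 0.5 under the
#'   range rules.
#' @examples
#' subjective_outcomes("RANGE", c(14, 50, 86), 1)      # 0, 0.5, 1
#' subjective_outcomes("DIVISIVE", c(14, 86), 1)       # 0.14, 0.86
#' @export
subjective_outcomes <- function(model, raw_outcomes, chosen_index = 1L,
                                params = NULL) {
  spec <- as_model_spec(model)
  m <- length(raw_outcomes)
  stopifnot(m >= 2, m <= 3, chosen_index >= 1, chosen_index <= m)
  switch(spec$model_id,
    UNBIASED = raw_outcomes,
    DIVISIVE = {
      s <- sum(raw_outcomes)
      if (s == 0) stop("divisive normalization undefined: outcomes sum to 0")
      raw_outcomes / s
    },
    {
      mn <- min(raw_outcomes); mx <- max(raw_outcomes)
      u <- if (mx == mn) rep(0.5, m) else (raw_outcomes - mn) / (mx - mn)
      if (spec$model_id == "RANGE_W") {
        u <- u ^ params$omega
      } else if (spec$model_id == "RANGE_WPLUS") {
        w <- rep(params$omega_u, m)
        w[chosen_index] <- params$omega_c
        u <- u ^ w
      }
      u
    })
}

#' Initialize a learner's value state
#'
#' @param model a [model_spec()] or model id.
#' @param option_ids identifiers of all options in the experiment.
#' @return a `value_state` list: `q`, the learned value per option
#'   (initialized at the model's `q_init`), and `last_seen`, the last
#'   displayed raw outcome per option (NA until first observation).
#' @export
value_state <- function(model, option_ids) {
  spec <- as_model_spec(model)
  structure(list(model_id = spec$model_id,
                 q = setNames(rep(spec$q_init, length(option_ids)),
                              option_ids),
                 last_seen = setNames(rep(NA_real_, length(option_ids)),
                                      option_ids)),
            class = "value_state")
}

#' Fill unobserved outcomes from memory (partial feedback)
#'
#' Under partial feedback only the obtained outcome is displayed; the
#' learner substitutes the last outcome it saw for each hidden option. An
#' option never yet observed falls back to 50 points, the midpoint of the
#' payoff scale (the raw-outcome counterpart of the models' neutral initial
#' value); the fallback is then normalized within the trial like any other
#' outcome. `last_seen` is updated with the outcomes actually displayed.
#'
#' @param state a [value_state()].
#' @param option_ids options presented on the trial.
#' @param raw_outcomes displayed outcomes, `NA` where hidden.
#' @return list with `outcomes` (complete raw vector) and the updated
#'   `state`.
#' @export
resolve_feedback <- function(state, option_ids, raw_outcomes) {
  stopifnot(length(option_ids) == length(raw_outcomes),
            any(!is.na(raw_outcomes)))
  filled <- raw_outcomes
  for (k in which(is.na(raw_outcomes))) {
    ls <- state$last_seen[[option_ids[k]]]
    filled[k] <- if (is.na(ls)) 50 else ls
  }
  obs <- which(!is.na(raw_outcomes))
  state$last_seen[option_ids[obs]] <- raw_outcomes[obs]
  list(outcomes = filled, state = state)
}

#' Delta-rule value update
#'
#' Each presented option's value moves toward its subjective outcome by a
#' prediction-error step: the obtained option with rate `alpha_c`, every
#' other presented option (including displayed-but-unavailable ones) with
#' rate `alpha_u`. Options not presented on the trial are untouched.
#'
#' @param state a [value_state()].
#' @param option_ids options presented on the trial.
#' @param u subjective outcomes from [subjective_outcomes()].
#' @param chosen_index position of the chosen (or forced) option.
#' @param params an [agent_parameters()] object.
#' @return the updated `value_state`.
#' @examples
#' st <- value_state("RANGE", c("a", "b"))
#' p <- agent_parameters("RANGE", 0.5, 0.2, 1)
#' update_values(st, c("a", "b"), c(0, 1), 2, p)$q  # 0.4, 0.75
#' @export
update_values <- function(state, option_ids, u, chosen_index, params) {
  stopifnot(length(option_ids) == length(u))
  alpha <- rep(params$alpha_u, length(u))
  alpha[chosen_index] <- params$alpha_c
  q <- state$q[option_ids]
  state$q[option_ids] <- q + alpha * (u - q)
  state
}

#' Softmax choice probabilities
#'
#' Probability of choosing each selectable option given current values and
#' inverse temperature `beta`; unavailable options receive probability 0.
#' Numerically stable for large `beta * q`.
#'
#' @param q_values numeric vector of learned values.
#' @param beta inverse temperature, >= 0 (`beta = 0` gives uniform choice).
#' @param available logical vector; defaults to all available.
#' @return probability vector summing to 1 over available options.
#' @examples
#' softmax_probabilities(c(0.2, 0.8), beta = 10)
#' @export
softmax_probabilities <- function(q_values, beta,
                                  available = rep(TRUE, length(q_values))) {
  stopifnot(beta >= 0, length(available) == length(q_values))
  if (!any(available)) stop("no available option")
  z <- beta * q_values[available]
  e <- exp(z - max(z))
  p <- numeric(length(q_values))
  p[available] <- e / sum(e)
  p
}

#' Argmax choice probability for a transfer pair
#'
#' Probability of choosing option a over option b from final learned values
#' under a greedy rule: 1 if `q_a > q_b`, 0.5 on a tie, 0 otherwise.
#'
#' @param q_a,q_b finite learned values of the two options.
#' @return 1, 0.5 or 0.
#' @export
argmax_choice_probability <- function(q_a, q_b) {
  stopifnot(is.finite(q_a), is.finite(q_b))
  if (q_a > q_b) 1 else if (q_a < q_b) 0 else 0.5
}
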