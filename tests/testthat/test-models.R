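test_that("model specs fix initialization and parameter sets", {
  expect_equal(model_spec("UNBIASED")$q_init, 50)
  for (m in c("DIVISIVE", "RANGE", "RANGE_W", "RANGE_WPLUS"))
    expect_equal(model_spec(m)$q_init, 0.5)
  expect_equal(model_spec("RANGE_WPLUS")$par_names,
               c("alpha_c", "alpha_u", "beta", "omega_c", "omega_u"))
  expect_error(model_spec("RANG"), "UNBIASED")
})

test_that("agent parameters are validated at construction", {
  expect_error(agent_parameters("RANGE", 1.2, 0.5, 1), "alpha_c")
  expect_error(agent_parameters("RANGE", 0.5, -0.1, 1), "alpha_u")
  expect_error(agent_parameters("RANGE", 0.5, 0.5, -1), "beta")
  expect_error(agent_parameters("RANGE_W", 0.5, 0.5, 1), "omega")
  expect_error(agent_parameters("RANGE_W", 0.5, 0.5, 1, omega = 0), "omega")
  expect_silent(agent_parameters("RANGE", 0, 1, 0))
})

test_that("normalization rules reproduce worked values", {
  expect_equal(subjective_outcomes("RANGE", c(14, 50, 86), 1), c(0, 0.5, 1))
  expect_equal(subjective_outcomes("DIVISIVE", c(14, 86), 1), c(0.14, 0.86))
  expect_equal(subjective_outcomes("UNBIASED", c(14, 86), 1), c(14, 86))
  pw <- agent_parameters("RANGE_W", 0.5, 0.5, 1, omega = 3)
  expect_equal(subjective_outcomes("RANGE_W", c(14, 50, 86), 1, pw)[2], 0.125)
  # degenerate range collapses to the midpoint value
  expect_equal(subjective_outcomes("RANGE", c(50, 50), 1), c(0.5, 0.5))
  expect_error(subjective_outcomes("DIVISIVE", c(0, 0), 1), "sum to 0")
})

test_that("normalization agrees with direct formula evaluation on random trials", {
  set.seed(42)
  for (rep in 1:1000) {
    m <- sample(2:3, 1)
    raw <- round(runif(m, 0, 100))
    if (max(raw) == min(raw)) next
    ch <- sample.int(m, 1)
    w <- exp(runif(2, -2, 2))
    pw <- agent_parameters("RANGE_W", 0.5, 0.5, 1, omega = w[1])
    pwp <- agent_parameters("RANGE_WPLUS", 0.5, 0.5, 1,
                            omega_c = w[1], omega_u = w[2])
    rng <- (raw - min(raw)) / (max(raw) - min(raw))
    expect_equal(subjective_outcomes("UNBIASED", raw, ch), raw,
                 tolerance = 1e-12)
    expect_equal(subjective_outcomes("DIVISIVE", raw, ch), raw / sum(raw),
                 tolerance = 1e-12)
    expect_equal(subjective_outcomes("RANGE", raw, ch), rng,
                 tolerance = 1e-12)
    expect_equal(subjective_outcomes("RANGE_W", raw, ch, pw), rng ^ w[1],
                 tolerance = 1e-12)
    wvec <- rep(w[2], m); wvec[ch] <- w[1]
    expect_equal(subjective_outcomes("RANGE_WPLUS", raw, ch, pwp),
                 rng ^ wvec, tolerance = 1e-12)
    # structural invariants
    expect_equal(sum(subjective_outcomes("DIVISIVE", raw, ch)), 1,
                 tolerance = 1e-12)
    expect_equal(range(rng), c(0, 1))
    pw1 <- agent_parameters("RANGE_W", 0.5, 0.5, 1, omega = 1)
    pwp1 <- agent_parameters("RANGE_WPLUS", 0.5, 0.5, 1,
                             omega_c = 1, omega_u = 1)
    expect_identical(subjective_outcomes("RANGE_W", raw, ch, pw1),
                     subjective_outcomes("RANGE", raw, ch))
    expect_identical(subjective_outcomes("RANGE_WPLUS", raw, ch, pwp1),
                     subjective_outcomes("RANGE", raw, ch))
  }
})

test_that("partial feedback fills hidden outcomes from memory", {
  st <- value_state("RANGE", c("A", "B"))
  # all observed: identity
  rf <- resolve_feedback(st, c("A", "B"), c(40, 49))
  expect_equal(rf$outcomes, c(40, 49))
  st <- rf$state
  # B hidden: last seen 49 substituted
  rf <- resolve_feedback(st, c("A", "B"), c(60, NA))
  expect_equal(rf$outcomes, c(60, 49))
  # never-observed option falls back to the 50-point scale midpoint
  st2 <- value_state("UNBIASED", c("A", "B"))
  rf2 <- resolve_feedback(st2, c("A", "B"), c(20, NA))
  expect_equal(rf2$outcomes, c(20, 50))
  expect_error(resolve_feedback(st2, c("A", "B"), c(NA_real_, NA_real_)))
})

test_that("delta-rule updates match one-step hand computation", {
  p <- agent_parameters("RANGE", 0.5, 0.2, 1)
  st <- value_state("RANGE", c("a", "b"))
  st <- update_values(st, c("a", "b"), c(0, 1), 2, p)
  expect_equal(unname(st$q), c(0.4, 0.75))
  # full-step learning
  p1 <- agent_parameters("RANGE", 1, 0.3, 1)
  st1 <- update_values(value_state("RANGE", "a"), "a", 0.8, 1, p1)
  expect_equal(unname(st1$q), 0.8)
  # zero learning rates leave values untouched
  p0 <- agent_parameters("UNBIASED", 0, 0, 1)
  st0 <- value_state("UNBIASED", c("a", "b"))
  expect_equal(update_values(st0, c("a", "b"), c(90, 10), 1, p0)$q, st0$q)
})

test_that("updates match a brute-force one-step oracle on random trials", {
  set.seed(7)
  for (rep in 1:1000) {
    m <- sample(2:3, 1)
    ids <- paste0("o", 1:m)
    q0 <- runif(m)
    u <- runif(m)
    ch <- sample.int(m, 1)
    ac <- runif(1); au <- runif(1)
    p <- agent_parameters("RANGE", ac, au, 1)
    st <- value_state("RANGE", ids)
    st$q[ids] <- q0
    got <- update_values(st, ids, u, ch, p)$q[ids]
    alpha <- ifelse(seq_len(m) == ch, ac, au)
    expect_equal(unname(got), q0 + alpha * (u - q0), tolerance = 1e-15)
  }
})

test_that("values stay in their model's range under repeated updates", {
  set.seed(11)
  p <- agent_parameters("RANGE", 0.9, 0.8, 1)
  st <- value_state("RANGE", c("a", "b", "c"))
  for (i in 1:200) {
    u <- runif(3)
    st <- update_values(st, c("a", "b", "c"), u, sample.int(3, 1), p)
    expect_true(all(st$q >= 0 & st$q <= 1))
  }
})

test_that("softmax behaves as the decision rule demands", {
  expect_equal(softmax_probabilities(c(1, 2, 3), beta = 0), rep(1 / 3, 3))
  expect_equal(softmax_probabilities(c(0.4, 0.4), beta = 7), c(0.5, 0.5))
  # direct formula evaluation
  p <- softmax_probabilities(c(0.2, 0.8), beta = 10)
  expect_equal(p[2], exp(8) / (exp(2) + exp(8)), tolerance = 1e-12)
  expect_equal(p[2], 0.9975274, tolerance = 1e-6)
  # availability masking
  pm <- softmax_probabilities(c(0.2, 0.8, 0.5), 3, c(TRUE, FALSE, TRUE))
  expect_equal(pm[2], 0)
  expect_equal(sum(pm), 1)
  expect_error(softmax_probabilities(c(1, 2), 1, c(FALSE, FALSE)), "available")
  # numerically stable at extreme sharpness
  pl <- softmax_probabilities(c(14, 86), beta = 148)
  expect_false(anyNA(pl))
  expect_equal(pl[2], 1)
})

test_that("raising beta never hurts the best available option", {
  set.seed(3)
  for (rep in 1:200) {
    q <- runif(3)
    avail <- c(TRUE, TRUE, sample(c(TRUE, FALSE), 1))
    betas <- sort(runif(2, 0, 30))
    best <- which(avail)[which.max(q[avail])]
    p_lo <- softmax_probabilities(q, betas[1], avail)
    p_hi <- softmax_probabilities(q, betas[2], avail)
    expect_gte(p_hi[best], p_lo[best] - 1e-12)
  }
})

test_that("argmax transfer rule implements the three branches exactly", {
  expect_equal(argmax_choice_probability(0.9, 0.1), 1)
  expect_equal(argmax_choice_probability(0.5, 0.5), 0.5)
  expect_equal(argmax_choice_probability(0.1, 0.9), 0)
  expect_error(argmax_choice_probability(NA, 1))
})

test_that("values converge to the mean subjective outcome under complete feedback", {
  # noiseless outcomes, 45 repetitions, moderate learning rates
  d <- bandit_design("1a")
  for (ct in names(d$contexts)) d$contexts[[ct]]$outcome_sd <- 0
  for (m in c("UNBIASED", "DIVISIVE", "RANGE")) {
    p <- agent_parameters(m, 0.4, 0.3, 5)
    s <- simulate_agent(d, m, p, seed = 2)
    for (ct in d$contexts) {
      mu <- ct$means
      u_target <- switch(m, UNBIASED = mu, DIVISIVE = mu / sum(mu),
                         (mu - min(mu)) / (max(mu) - min(mu)))
      scale <- if (m == "UNBIASED") 100 else 1
      expect_true(all(abs(s$final_state$q[ct$option_ids] - u_target) <
                        0.01 * scale))
    }
  }
})
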