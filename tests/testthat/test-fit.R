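test_that("uniform-policy likelihood equals its analytic value", {
  coh <- simulate_cohort("RANGE", design_1a, 1, seed = 2)
  p0 <- agent_parameters("RANGE", 0.5, 0.5, 0)
  # design 1a: 90 binary + 90 trinary free learning trials
  expect_equal(learning_negloglik(p0, "RANGE", coh$trials),
               90 * log(2) + 90 * log(3), tolerance = 1e-12)
  # beta = 0 makes the model identity irrelevant
  expect_equal(learning_negloglik(agent_parameters("UNBIASED", 0.5, 0.5, 0),
                                  "UNBIASED", coh$trials),
               90 * log(2) + 90 * log(3), tolerance = 1e-12)
})

test_that("likelihood replay matches the brute-force oracle", {
  set.seed(31)
  for (gen in c("UNBIASED", "RANGE", "RANGE_W")) {
    pr <- sample_agent_parameters(gen)
    s <- simulate_agent(bandit_design("1c"), gen, pr,
                        seed = sample.int(1e6, 1))
    for (fit_model in c("UNBIASED", "DIVISIVE", "RANGE", "RANGE_WPLUS")) {
      for (rep in 1:5) {
        pt <- random_point()
        got <- learning_negloglik(oracle_params(fit_model, pt), fit_model,
                                  s$trials)
        want <- oracle_negloglik(pt, fit_model, s$trials)
        expect_equal(got, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("replay handles displayed-but-unavailable options like the oracle", {
  set.seed(77)
  pr <- sample_agent_parameters("RANGE")
  s <- simulate_agent(bandit_design("3b"), "RANGE", pr, seed = 13)
  for (rep in 1:10) {
    pt <- random_point()
    for (m in c("RANGE", "DIVISIVE", "RANGE_WPLUS")) {
      expect_equal(learning_negloglik(oracle_params(m, pt), m, s$trials),
                   oracle_negloglik(pt, m, s$trials), tolerance = 1e-9)
    }
  }
})

test_that("true parameters beat perturbed ones on average", {
  set.seed(5)
  wins <- 0L
  n_sub <- 20L
  for (i in seq_len(n_sub)) {
    pr <- agent_parameters("RANGE", runif(1, 0.2, 0.8), runif(1, 0.2, 0.8),
                           runif(1, 2, 10))
    s <- simulate_agent(design_1a, "RANGE", pr, seed = sample.int(1e6, 1))
    nll_true <- learning_negloglik(pr, "RANGE", s$trials)
    pert <- agent_parameters("RANGE", min(1, pr$alpha_c * 1.5),
                             min(1, pr$alpha_u * 1.5), pr$beta * 0.5)
    nll_pert <- learning_negloglik(pert, "RANGE", s$trials)
    wins <- wins + (nll_true <= nll_pert)
  }
  expect_gte(wins / n_sub, 0.9)
})

test_that("fitting is deterministic and never worsens with more restarts", {
  coh <- simulate_cohort("RANGE", design_1a, 1, seed = 17)
  f1 <- fit_bandit(coh$trials, "RANGE", n_restarts = 3, seed = 4)
  f2 <- fit_bandit(coh$trials, "RANGE", n_restarts = 3, seed = 4)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$oos_loglik, f2$oos_loglik)
  f0 <- fit_bandit(coh$trials, "RANGE", n_restarts = 1, seed = 4)
  expect_lte(-f1$learning_loglik, -f0$learning_loglik + 1e-9)
  # parameters respect their bounds
  expect_true(coef(f1)[["alpha_c"]] >= 0 && coef(f1)[["alpha_c"]] <= 1)
  expect_true(coef(f1)[["beta"]] > 0)
  expect_true(f1$converged)
  expect_equal(f1$n_restarts_used, 3L)
})

test_that("zero-information data drives beta toward the chance bound", {
  coh <- simulate_cohort("RANGE", design_1a, 1, seed = 23)
  tr <- coh$trials
  # scramble the choices so they carry no value signal
  lt <- tr$phase == "learning"
  set.seed(1)
  for (i in which(lt)) {
    ids <- unlist(tr[i, paste0("option", 1:3)])
    av <- unlist(tr[i, paste0("available", 1:3)])
    ids <- ids[!is.na(ids) & av]
    tr$choice[i] <- sample(ids, 1)
  }
  f <- fit_bandit(tr, "RANGE", n_restarts = 5, seed = 2)
  chance <- -(90 * log(2) + 90 * log(3))
  expect_lt(abs(f$learning_loglik - chance), 6)
})

test_that("transfer out-of-sample likelihood has its analytic limits", {
  coh <- simulate_cohort("RANGE", design_1a, 1, seed = 29)
  tr <- coh$trials[coh$trials$phase == "transfer", ]
  q <- coh$final_q[1, ]
  # beta = 0: uniform over each pair
  expect_equal(transfer_oos_loglik(list(final_q = q, par = c(beta = 0)), tr),
               180 * log(0.5), tolerance = 1e-12)
  # choices consistent with argmax on well-separated values, huge beta:
  # near-zero loss
  q2 <- setNames(0.1 * seq_along(q), names(q))
  tr2 <- tr
  tr2$choice <- ifelse(q2[tr2$option1] >= q2[tr2$option2], tr2$option1,
                       tr2$option2)
  ll <- transfer_oos_loglik(list(final_q = q2, par = c(beta = 1000)), tr2)
  expect_gt(ll, -1e-6)
  # empty transfer set contributes nothing
  expect_equal(transfer_oos_loglik(list(final_q = q, par = c(beta = 1)),
                                   tr[0, ]), 0)
  # unknown cue is an error
  tr3 <- tr
  tr3$option1[1] <- "nope"
  expect_error(transfer_oos_loglik(list(final_q = q, par = c(beta = 1)),
                                   tr3), "nope")
})

test_that("bandit_fit methods expose the fit like a classed model object", {
  coh <- simulate_cohort("RANGE", design_1a, 1, seed = 37)
  f <- fit_bandit(coh$trials, "RANGE", n_restarts = 3, seed = 1)
  expect_s3_class(f, "bandit_fit")
  expect_named(coef(f), c("alpha_c", "alpha_u", "beta"))
  ll <- logLik(f)
  expect_equal(attr(ll, "nobs"), 180L)
  expect_equal(attr(ll, "df"), 3L)
  expect_output(print(f), "RANGE")
  expect_output(print(summary(f)), "final learned values")
  p_tr <- predict(f, "transfer")
  expect_length(p_tr, 180L)
  expect_true(all(p_tr > 0 & p_tr < 1))
  expect_equal(sum(log(p_tr)), f$oos_loglik, tolerance = 1e-9)
  p_lrn <- predict(f, "learning")
  expect_length(p_lrn, 180L)
  expect_equal(sum(log(p_lrn)), f$learning_loglik, tolerance = 1e-9)
  expect_equal(residuals(f), 1 - p_tr)
  sims <- simulate(f, nsim = 2, seed = 3)
  expect_length(sims, 2L)
  expect_equal(nrow(sims[[1]]), 180L + 180L + 40L)
})

test_that("cohort fitting returns one row per subject and model", {
  coh <- simulate_cohort("RANGE", design_1a, 2, seed = 41)
  fits <- fit_cohort(coh$trials, models = c("UNBIASED", "RANGE"),
                     n_restarts = 2, seed = 1)
  expect_equal(nrow(fits), 4L)
  expect_setequal(fits$model_id, c("UNBIASED", "RANGE"))
  expect_true(all(fits$learning_loglik <= 0))
  expect_true(all(fits$oos_loglik <= 0))
  expect_true(all(fits$converged))
})

test_that("degenerate fitting inputs raise clear errors", {
  coh <- simulate_cohort("RANGE", design_1a, 1, seed = 43)
  expect_error(fit_bandit(coh$trials[coh$trials$phase == "transfer", ],
                          "RANGE"), "no learning-phase trials")
  tr <- coh$trials
  tr$choice[tr$phase == "learning"][3] <- NA
  expect_error(learning_negloglik(agent_parameters("RANGE", .5, .5, 1),
                                  "RANGE", tr), "without a recorded choice")
})
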