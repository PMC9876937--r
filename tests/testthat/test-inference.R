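# brute-force AICc/weight panel used as the independent oracle throughout
brute_panel <- function(loglik, k, n) {
  a <- -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  d <- a - min(a)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  list(aicc = a, delta = d, weight = w, er = exp(d / 2))
}

fake_fit <- function(terms, loglik, k, n) {
  list(terms = terms, logLik = loglik, k = k, n = n)
}

test_that("coefficients match ordinary least squares when variances vanish", {
  # runs carry no effect here since the fitted model omits the run term
  p <- true_model_params(sd_individual_intercept = 0,
                         sd_individual_slope = 0, sd_residual = 1e-4,
                         run_effects = rep(0, 4))
  rec <- simulate_rmr_records(p, n_forest = 4, n_urban = 4,
                              days_per_individual = 2, seed = 8)
  terms <- c("t_nest_int", "habitat", "diel", "habitat:t_nest_int")
  fit <- fit_lmm(rec, terms, method = "ML", random_slope = FALSE,
                 nest_housing = FALSE)
  d <- rec
  d$habitat <- relevel(factor(d$habitat), "forest")
  d$diel <- relevel(factor(d$diel), "day")
  ols <- lm(rmr_mass_specific ~ diel + habitat + t_nest_int +
              habitat:t_nest_int, data = d)
  expect_true(fit$singular)
  expect_equal(fit$coefficients[names(coef(ols)), "estimate"],
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("candidate enumeration yields the marginality-respecting lattice", {
  cand <- enumerate_candidates(c("A", "B"), "A:B")
  expect_length(cand, 5)
  expect_true(any(vapply(cand, function(s) length(s) == 0, logical(1))))
  expect_true(any(vapply(cand, function(s) setequal(s, c("A", "B", "A:B")),
                         logical(1))))
  # no interactions: plain power set
  expect_length(enumerate_candidates(letters[1:4]), 2^4)
  # marginality: an interaction never appears without both parents
  full <- enumerate_candidates(
    c("t_nest_int", "habitat", "diel", "run", "housing_half"),
    c("habitat:t_nest_int", "habitat:run"))
  for (s in full) {
    for (ia in intersect(s, c("habitat:t_nest_int", "habitat:run"))) {
      expect_true(all(strsplit(ia, ":")[[1]] %in% s))
    }
  }
  # independent count: subsets of 5 mains, times 2 per admissible interaction
  n_expect <- 0
  for (i in 0:31) {
    ms <- c("t_nest_int", "habitat", "diel", "run",
            "housing_half")[bitwAnd(i, 2^(0:4)) > 0]
    n_expect <- n_expect +
      2^(("habitat" %in% ms && "t_nest_int" %in% ms) +
           ("habitat" %in% ms && "run" %in% ms))
  }
  expect_length(full, n_expect)
  # deterministic order
  expect_identical(full, enumerate_candidates(
    c("t_nest_int", "habitat", "diel", "run", "housing_half"),
    c("habitat:t_nest_int", "habitat:run")))
  # candidate list covers the study's reported model structures
  expect_true(any(vapply(full, setequal,
                         y = c("t_nest_int", "habitat", "diel",
                               "habitat:t_nest_int"), logical(1))))
  expect_true(any(vapply(full, setequal,
                         y = c("t_nest_int", "habitat", "diel", "run",
                               "habitat:t_nest_int"), logical(1))))
  expect_error(enumerate_candidates("A", "A:B"), "parent")
})

test_that("selection table matches brute-force AICc recomputation", {
  set.seed(31)
  n <- 500
  loglik <- 1200 + rnorm(12, 0, 3)
  k <- sample(5:14, 12, replace = TRUE)
  fits <- lapply(seq_along(loglik), function(i) {
    fake_fit(letters[seq_len(i %% 4 + 1)], loglik[i], k[i], n)
  })
  sel <- build_selection_table(fits)
  oracle <- brute_panel(loglik, k, n)
  ord <- order(oracle$aicc)
  expect_equal(sel$table$aicc, oracle$aicc[ord], tolerance = 1e-12)
  expect_equal(sel$table$delta_aicc, oracle$delta[ord], tolerance = 1e-12)
  expect_equal(sel$table$weight, oracle$weight[ord], tolerance = 1e-12)
  expect_equal(sel$table$evidence_ratio, oracle$er[ord], tolerance = 1e-12)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_equal(sel$table$delta_aicc[1], 0)
  expect_equal(sel$table$evidence_ratio[1], 1)
  # ER identity against the weight ratio
  expect_equal(sel$table$evidence_ratio,
               sel$table$weight[1] / sel$table$weight, tolerance = 1e-10)
  # variable weights: independent recomputation for one term
  w_a <- sum(oracle$weight[vapply(fits, function(f) "a" %in% f$terms,
                                  logical(1))])
  expect_equal(unname(sel$variable_weights["a"]), w_a, tolerance = 1e-12)
})

test_that("the confidence set is the minimal top-ranked prefix", {
  set.seed(7)
  for (rep in 1:20) {
    nf <- sample(3:15, 1)
    fits <- lapply(seq_len(nf), function(i) {
      fake_fit(letters[i], 100 + rnorm(1, 0, 2), 5, 200)
    })
    sel <- build_selection_table(fits, conf_level = 0.95)
    m <- sum(sel$table$in_confidence_set)
    expect_gte(sel$table$cum_weight[m], 0.95)
    if (m > 1) expect_lt(sel$table$cum_weight[m - 1], 0.95)
  }
  one <- build_selection_table(list(fake_fit("a", 50, 4, 100)))
  expect_equal(one$table$weight, 1)
  expect_equal(one$table$evidence_ratio, 1)
  expect_true(one$table$in_confidence_set)
})

test_that("fits on differing record sets are rejected as incomparable", {
  fits <- list(fake_fit("a", 100, 5, 200), fake_fit("b", 101, 5, 199))
  expect_error(build_selection_table(fits), "incomparable")
})

test_that("ICC reflects the intercept share of random plus residual variance", {
  # run effects are zeroed: the fitted model omits run, and a nonzero
  # between-run offset would inflate the intercept variance it estimates
  p <- true_model_params(sd_individual_intercept = 0.08,
                         sd_individual_slope = 0, sd_residual = 0.08,
                         run_effects = rep(0, 4))
  rec <- simulate_rmr_records(p, n_forest = 30, n_urban = 30,
                              days_per_individual = 4, seed = 19)
  eff <- effect_sizes(rec, c("t_nest_int", "habitat", "diel"),
                      random_slope = FALSE, nest_housing = FALSE)
  expect_equal(eff$icc, 0.5, tolerance = 0.12)
  expect_gte(eff$r2_conditional, eff$r2_marginal)
  expect_lte(eff$r2_conditional, 1)
  expect_gte(eff$r2_marginal, 0)
})

test_that("Cohen's f2 carries the sign of the predictor's coefficient", {
  p <- true_model_params()
  rec <- simulate_rmr_records(p, seed = 23)
  terms <- c("t_nest_int", "habitat", "diel", "habitat:t_nest_int")
  eff <- effect_sizes(rec, terms)
  cs <- eff$fit$coefficients
  expect_lt(cs["habitaturban", "estimate"], 0)
  expect_lte(eff$f2[["habitat"]], 0)
  expect_gt(cs["dielnight", "estimate"], 0)
  expect_gte(eff$f2[["diel"]], 0)
})

test_that("AICc identity holds on a fitted candidate", {
  p <- true_model_params()
  rec <- simulate_rmr_records(p, n_forest = 3, n_urban = 3,
                              days_per_individual = 2, seed = 2)
  fit <- fit_lmm(rec, c("t_nest_int", "diel"), method = "ML")
  expect_equal(fit$aicc,
               -2 * fit$logLik + 2 * fit$k +
                 2 * fit$k * (fit$k + 1) / (fit$n - fit$k - 1))
  expect_lt(fit$k, fit$n - 1)
})

test_that("a null interaction is rarely promoted by AICc", {
  p0 <- true_model_params(beta_interaction = 0)
  terms_base <- c("t_nest_int", "habitat", "diel")
  wins <- 0L
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    rec <- suppressWarnings(simulate_rmr_records(p0, seed = 3000 + i))
    f1 <- suppressWarnings(fit_lmm(rec, terms_base, method = "ML"))
    f2 <- suppressWarnings(
      fit_lmm(rec, c(terms_base, "habitat:t_nest_int"), method = "ML"))
    sel <- build_selection_table(list(f1, f2))
    if (grepl("habitat:t_nest_int", sel$table$terms[1])) wins <- wins + 1L
  }
  expect_lte(wins / n_rep, 0.25)
})
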