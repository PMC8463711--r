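# Shared small synthetic setup: 6 states x 40 species with planted effects.
make_recovery_setup <- function(seed = 101, noise_sd = 0.05,
                                gamma_body = 0.05, gamma_flock = 0,
                                gamma_color = 0, gamma_iucn = 0,
                                n_states = 6, n_species = 40,
                                effort = 2e5) {
  states <- sprintf("s%02d", seq_len(n_states))
  tr <- generate_traits(trait_gen_config(n_species, seed = seed))
  tt <- build_trait_table(tr$species, patches = tr$patches)
  truth <- planted_effects(states, gamma_body = gamma_body,
                           gamma_flock = gamma_flock,
                           gamma_color = gamma_color,
                           gamma_iucn = gamma_iucn,
                           noise_sd = noise_sd, seed = seed)
  counts <- generate_counts_direct(
    tt, states, stats::setNames(rep(effort, n_states), states), truth,
    seed = seed)
  resid_tbl <- suppressWarnings(build_residual_table(counts))
  list(trait_tbl = tt, truth = truth, counts = counts,
       residuals = resid_tbl)
}

test_that("model frames resolve trait completeness per model", {
  su <- make_recovery_setup(seed = 55)
  tt <- su$trait_tbl
  # plan: 5 species lose color, 3 (other) species lose flock
  tt$color_index[1:5] <- NA
  tt$log10_flock_size[6:8] <- NA
  global <- assemble_model_frame(su$residuals, tt)
  body_only <- assemble_model_frame(su$residuals, tt,
                                    model_spec("log10_body_mass"))
  color_only <- assemble_model_frame(su$residuals, tt,
                                     model_spec("color_index"))
  dropped_species <- tt$species[1:8]
  expect_false(any(global$species %in% dropped_species))
  expect_true(any(body_only$species %in% dropped_species))
  n_rows_per_missing <- sum(su$residuals$species %in% dropped_species)
  expect_equal(attr(global, "n_dropped"), n_rows_per_missing)
  expect_equal(attr(color_only, "n_dropped"),
               sum(su$residuals$species %in% tt$species[1:5]))
  expect_gt(nrow(body_only), nrow(global))
})

test_that("unknown predictors and empty frames are rejected", {
  su <- make_recovery_setup(seed = 56, n_states = 3, n_species = 10)
  expect_error(model_spec("wingspan"), "unknown predictor")
  tt <- su$trait_tbl
  tt$color_index <- NA_real_
  expect_error(assemble_model_frame(su$residuals, tt), "empty")
})

test_that("a single-state frame degenerates to ordinary least squares", {
  # enough species that all three retained IUCN levels are present
  su <- make_recovery_setup(seed = 57, n_states = 1, n_species = 120)
  frame <- assemble_model_frame(su$residuals, su$trait_tbl)
  fit <- fit_mixed(frame)
  expect_match(fit$method, "ols")
  expect_equal(fit$random_intercept_variance, 0)
  ols <- stats::lm(residual ~ log10_body_mass + log10_flock_size +
                     color_index + iucn_score, data = frame)
  expect_equal(fit$fixed_effects$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("near-zero random-intercept variance reproduces OLS fixed effects", {
  su <- make_recovery_setup(seed = 58, n_states = 5)
  frame <- assemble_model_frame(su$residuals, su$trait_tbl)
  fit <- suppressMessages(fit_mixed(frame))
  # per-state OLS centers residuals, so the state variance collapses
  expect_lt(fit$random_intercept_variance, 1e-6)
  ols <- stats::lm(residual ~ log10_body_mass + log10_flock_size +
                     color_index + iucn_score, data = frame)
  expect_equal(fit$fixed_effects$estimate, unname(stats::coef(ols)),
               tolerance = 1e-6)
})

test_that("estimates are invariant to row order and state relabeling", {
  su <- make_recovery_setup(seed = 59)
  frame <- assemble_model_frame(su$residuals, su$trait_tbl)
  a <- suppressMessages(fit_mixed(frame))
  perm <- withr::with_seed(1, sample(nrow(frame)))
  shuffled <- frame[perm, ]
  shuffled$state <- paste0("renamed_", shuffled$state)
  b <- suppressMessages(fit_mixed(shuffled))
  expect_equal(a$fixed_effects$estimate, b$fixed_effects$estimate,
               tolerance = 1e-8)
  expect_equal(a$fixed_effects$std_error, b$fixed_effects$std_error,
               tolerance = 1e-8)
})

test_that("constant predictors are refused by name", {
  su <- make_recovery_setup(seed = 60, n_states = 3, n_species = 12)
  tt <- su$trait_tbl
  tt$color_index <- 0.5
  frame <- assemble_model_frame(su$residuals, tt)
  expect_error(fit_mixed(frame), "color_index")
})

test_that("fixed-effect intervals bracket the estimate and variances are nonnegative", {
  su <- make_recovery_setup(seed = 61)
  frame <- assemble_model_frame(su$residuals, su$trait_tbl)
  fit <- suppressMessages(fit_mixed(frame))
  fe <- fit$fixed_effects
  expect_true(all(fe$ci_low <= fe$estimate & fe$estimate <= fe$ci_high))
  expect_gte(fit$random_intercept_variance, 0)
  expect_gt(fit$residual_variance, 0)
  expect_equal(fit$n_rows, nrow(frame))
  expect_output(print(fit), "Residual-on-traits")
})

test_that("planted signs (+, +, 0, +) are recovered qualitatively", {
  su <- make_recovery_setup(seed = 62, gamma_body = 0.05,
                            gamma_flock = 0.05, gamma_color = 0,
                            gamma_iucn = 0.03, n_states = 10,
                            n_species = 100)
  fits <- suppressMessages(fit_all(su$residuals, su$trait_tbl))
  fe <- fits$global$fixed_effects
  est <- function(term) fe$estimate[fe$term == term]
  expect_gt(est("log10_body_mass"), 0)
  expect_gt(est("log10_flock_size"), 0)
  expect_gt(est("iucn_score"), 0)
  expect_lt(abs(est("color_index")), 0.02)
  # orthogonal planted predictors: global and single-trait fits agree up
  # to omitted-variable leakage through finite-sample trait correlations
  # (of order gamma / sqrt(n_species), so well inside 0.05 here)
  ag <- fits$sign_agreement
  expect_false(any(ag$sign_mismatch))
  expect_lt(max(abs(ag$global_estimate - ag$single_estimate)), 0.05)
  # single-trait models can only gain rows relative to the global model
  for (res in fits$per_trait) {
    expect_gte(res$n_rows, fits$global$n_rows)
  }
})

test_that("recovery simulation and report wire truth through to summaries", {
  rec <- simulate_recovery(n_reps = 2, n_states = 6, n_species = 40,
                           seed_offset = 7000)
  expect_equal(nrow(rec$estimates), 2 * 4)
  rep_tbl <- recovery_report(rec$estimates, rec$truth)
  expect_setequal(rep_tbl$term,
                  c("log10_body_mass", "log10_flock_size", "color_index",
                    "iucn_score"))
  expect_equal(rep_tbl$n_reps, rep(2, 4))
  expect_equal(rep_tbl$truth[rep_tbl$term == "log10_body_mass"], 0.05)
  expect_true(all(rep_tbl$rmse >= abs(rep_tbl$bias)))
})
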