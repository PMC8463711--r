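# Linear mixed models of the representation residual on species traits,
# with a random intercept per state, plus the parameter-recovery harness
# used to validate the whole pipeline on synthetic data.

TRAIT_PREDICTORS <- c("log10_body_mass", "log10_flock_size", "color_index",
                      "iucn_score")

#' Specification of a residual-on-traits model
#'
#' @param predictors Ordered subset of the four trait predictors
#'   (`log10_body_mass`, `log10_flock_size`, `color_index`, `iucn_score`).
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param ci_level Confidence level for the fixed-effect Wald intervals.
#' @return A `model_spec` list.
#' @export
model_spec <- function(predictors = TRAIT_PREDICTORS,
                       estimation = c("REML", "ML"), ci_level = 0.95) {
  estimation <- match.arg(estimation)
  predictors <- as.character(predictors)
  if (!length(predictors)) stop("'predictors' must be non-empty",
                                call. = FALSE)
  bad <- setdiff(predictors, TRAIT_PREDICTORS)
  if (length(bad)) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(TRAIT_PREDICTORS, collapse = ", "),
         call. = FALSE)
  }
  assert_number(ci_level, "ci_level", lower = 1e-6, upper = 1 - 1e-6)
  structure(list(predictors = predictors, estimation = estimation,
                 ci_level = ci_level), class = "model_spec")
}

#' Join residuals to traits into a model frame
#'
#' One row per (state, species) with the residual and the requested
#' predictors. Rows missing any required predictor are dropped per model,
#' so single-trait models may keep more rows than the global model; the
#' number of dropped rows is attached as the `n_dropped` attribute.
#'
#' @param residuals Residual table from [build_residual_table()].
#' @param trait_tbl Trait vector table ([build_trait_table()] output).
#' @param spec A [model_spec()].
#' @return Tibble: `state`, `species`, `residual`, and the predictors.
#' @export
assemble_model_frame <- function(residuals, trait_tbl,
                                 spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  missing_cols <- setdiff(spec$predictors, names(trait_tbl))
  if (length(missing_cols)) {
    stop("trait table is missing predictor(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  frame <- dplyr::inner_join(
    residuals[, c("state", "species", "residual")],
    trait_tbl[, c("species", spec$predictors)], by = "species")
  complete <- stats::complete.cases(frame[, spec$predictors])
  out <- frame[complete, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("model frame is empty after dropping rows with missing traits",
         call. = FALSE)
  }
  attr(out, "n_dropped") <- sum(!complete)
  out
}

wald_ci <- function(est, se, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(ci_low = est - z * se, ci_high = est + z * se)
}

#' Fit the residual-on-traits mixed model
#'
#' Linear mixed model with the spec's predictors as fixed effects and a
#' random intercept per state (absorbing state-level effort, avifauna and
#' observer-base differences, and the replication of species across
#' states). Estimation is REML by default; confidence intervals are Wald
#' intervals on the fixed effects and p-values use Satterthwaite
#' approximated degrees of freedom. With a single state the random
#' intercept is unidentifiable and the model degenerates to ordinary least
#' squares on the same frame (`method = "ols"`), with zero random-intercept
#' variance.
#'
#' @param frame Model frame from [assemble_model_frame()].
#' @param spec A [model_spec()].
#' @return A `mixed_model_result`: `fixed_effects` tibble (term, estimate,
#'   std_error, ci_low, ci_high, df, p_value), variance components, sizes,
#'   convergence flags, and method strings.
#' @export
fit_mixed <- function(frame, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  preds <- spec$predictors
  sds <- vapply(frame[preds], stats::sd, numeric(1))
  if (any(sds == 0 | is.na(sds))) {
    stop("constant predictor(s): ",
         paste(preds[sds == 0 | is.na(sds)], collapse = ", "),
         call. = FALSE)
  }
  n_states <- length(unique(frame$state))
  if (n_states < 2) {
    fit <- stats::lm(stats::reformulate(preds, response = "residual"),
                     data = frame)
    sm <- summary(fit)$coefficients
    ci <- wald_ci(sm[, 1], sm[, 2], spec$ci_level)
    fe <- tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, 1]),
      std_error = unname(sm[, 2]),
      ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
      df = stats::df.residual(fit), p_value = unname(sm[, 4]))
    result <- list(fixed_effects = fe, random_intercept_variance = 0,
                   residual_variance = summary(fit)$sigma^2,
                   converged = TRUE, singular = FALSE,
                   method = "ols (single state; random intercept dropped)")
  } else {
    form <- stats::as.formula(
      paste("residual ~", paste(preds, collapse = " + "), "+ (1 | state)"))
    fit <- lmerTest::lmer(form, data = frame,
                          REML = spec$estimation == "REML")
    sm <- summary(fit)$coefficients
    ci <- wald_ci(sm[, "Estimate"], sm[, "Std. Error"], spec$ci_level)
    vc <- as.data.frame(lme4::VarCorr(fit))
    fe <- tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"]),
      ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
      df = unname(sm[, "df"]), p_value = unname(sm[, "Pr(>|t|)"]))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    result <- list(
      fixed_effects = fe,
      random_intercept_variance = vc$vcov[vc$grp == "state"],
      residual_variance = vc$vcov[vc$grp == "Residual"],
      converged = conv, singular = lme4::isSingular(fit),
      method = paste0("lmm-", tolower(spec$estimation),
                      " (satterthwaite df)"))
  }
  result$ci_method <- paste0("wald-z (", spec$ci_level * 100, "%)")
  result$n_rows <- nrow(frame)
  result$n_species <- length(unique(frame$species))
  result$n_states <- n_states
  result$spec <- spec
  structure(result, class = "mixed_model_result")
}

#' @export
#' @method print mixed_model_result
print.mixed_model_result <- function(x, ...) {
  cat("Residual-on-traits model (", x$method, ")\n", sep = "")
  cat("  rows:", x$n_rows, " species:", x$n_species,
      " states:", x$n_states, "\n")
  cat("  random-intercept var:", signif(x$random_intercept_variance, 4),
      " residual var:", signif(x$residual_variance, 4), "\n")
  print(as.data.frame(x$fixed_effects), digits = 4)
  invisible(x)
}

#' Fit the global model and the four single-trait models
#'
#' The global model includes all four predictors simultaneously; the four
#' single-trait models use one predictor each (and, because completeness is
#' resolved per model, may include more rows). Sign disagreement between a
#' global estimate and its single-trait counterpart is flagged when both
#' intervals exclude zero.
#'
#' @param residuals Residual table.
#' @param trait_tbl Trait vector table.
#' @param spec A [model_spec()] for the global model; single-trait models
#'   inherit its estimation and CI level.
#' @return List: `global` result, `per_trait` named list of results, and a
#'   `sign_agreement` tibble.
#' @export
fit_all <- function(residuals, trait_tbl, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  global_frame <- assemble_model_frame(residuals, trait_tbl, spec)
  global <- fit_mixed(global_frame, spec)
  per_trait <- list()
  agree <- list()
  for (p in spec$predictors) {
    sp1 <- model_spec(p, estimation = spec$estimation,
                      ci_level = spec$ci_level)
    fr <- assemble_model_frame(residuals, trait_tbl, sp1)
    per_trait[[p]] <- fit_mixed(fr, sp1)
    g <- global$fixed_effects[global$fixed_effects$term == p, ]
    s <- per_trait[[p]]$fixed_effects[
      per_trait[[p]]$fixed_effects$term == p, ]
    both_sig <- (g$ci_low > 0 | g$ci_high < 0) &
      (s$ci_low > 0 | s$ci_high < 0)
    agree[[p]] <- tibble::tibble(
      term = p, global_estimate = g$estimate,
      single_estimate = s$estimate,
      sign_mismatch = both_sig & sign(g$estimate) != sign(s$estimate))
  }
  list(global = global, per_trait = per_trait,
       sign_agreement = dplyr::bind_rows(agree))
}

TERM_TO_GAMMA <- c(log10_body_mass = "gamma_body",
                   log10_flock_size = "gamma_flock",
                   color_index = "gamma_color",
                   iucn_score = "gamma_iucn")

#' Run a parameter-recovery simulation
#'
#' Repeatedly generates trait tables and paired counts with planted
#' effects, runs the residual statistic and the global mixed model, and
#' collects the four trait estimates with intervals and p-values. The
#' replicate seeds are `seed_offset + 1 .. seed_offset + n_reps`, so a run
#' is exactly reproducible.
#'
#' @param n_reps Number of replicates.
#' @param n_states,n_species Design size per replicate.
#' @param gamma_body,gamma_flock,gamma_color,gamma_iucn,noise_sd Planted
#'   truth passed to [planted_effects()].
#' @param effort_meanlog,effort_sdlog Log-normal state effort. The default
#'   (median 200,000 per state) puts the simulated semi-structured volume at
#'   the order of the real aggregate extracts (about 1e8 records) so that
#'   counts are large and integer rounding of the generated unstructured
#'   counts is negligible against `noise_sd`; at much smaller scales the
#'   rounding grid induces species-correlated errors outside the fitted
#'   model (see the methods vignette).
#' @param seed_offset Added to the replicate index to form each seed.
#' @param zero_policy Passed to [build_residual_table()].
#' @return List: `estimates` tibble (replicate, term, estimate, std_error,
#'   ci_low, ci_high, p_value) and `truth` (the planted gamma values).
#' @export
simulate_recovery <- function(n_reps = 20, n_states = 40, n_species = 150,
                              gamma_body = 0.05, gamma_flock = 0.05,
                              gamma_color = 0, gamma_iucn = 0.03,
                              noise_sd = 0.05,
                              effort_meanlog = log(2e5), effort_sdlog = 0.5,
                              seed_offset = 0L,
                              zero_policy = "drop") {
  states <- sprintf("state%02d", seq_len(n_states))
  truth_gammas <- c(gamma_body = gamma_body, gamma_flock = gamma_flock,
                    gamma_color = gamma_color, gamma_iucn = gamma_iucn)
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    seed <- as.integer(seed_offset + r)
    traits <- generate_traits(trait_gen_config(n_species, seed = seed))
    trait_tbl <- build_trait_table(traits$species,
                                   patches = traits$patches)
    truth <- planted_effects(states, gamma_body = gamma_body,
                             gamma_flock = gamma_flock,
                             gamma_color = gamma_color,
                             gamma_iucn = gamma_iucn,
                             noise_sd = noise_sd, seed = seed)
    withr::with_seed(substream_seed(seed, 5L), {
      effort <- stats::rlnorm(n_states, effort_meanlog, effort_sdlog)
    })
    names(effort) <- states
    counts <- generate_counts_direct(trait_tbl, states, effort, truth,
                                     seed = seed)
    resid_tbl <- suppressWarnings(
      build_residual_table(counts, zero_policy = zero_policy))
    frame <- assemble_model_frame(resid_tbl, trait_tbl)
    # singular fits are expected: per-state OLS centers the residuals, so
    # little state-level variance remains for the random intercept
    fit <- suppressMessages(fit_mixed(frame))
    fe <- fit$fixed_effects
    fe <- fe[fe$term %in% names(TERM_TO_GAMMA), ]
    fe$replicate <- r
    rows[[r]] <- fe[, c("replicate", "term", "estimate", "std_error",
                        "ci_low", "ci_high", "p_value")]
  }
  list(estimates = dplyr::bind_rows(rows), truth = truth_gammas)
}

#' Summarise recovery of planted effects
#'
#' Per trait: mean estimate, bias, RMSE, empirical coverage of the
#' confidence intervals, and the rejection rate of the 5%-level test
#' (meaningful as a type-I error rate for traits planted at zero).
#'
#' @param estimates Estimates tibble from [simulate_recovery()].
#' @param truth Named vector of planted gammas (`gamma_body`, ...).
#' @return Tibble with one row per trait term.
#' @export
recovery_report <- function(estimates, truth) {
  terms <- intersect(names(TERM_TO_GAMMA), unique(estimates$term))
  rows <- lapply(terms, function(p) {
    g <- truth[[TERM_TO_GAMMA[[p]]]]
    e <- estimates[estimates$term == p, ]
    tibble::tibble(
      term = p, truth = g, n_reps = nrow(e),
      mean_estimate = mean(e$estimate),
      bias = mean(e$estimate) - g,
      rmse = sqrt(mean((e$estimate - g)^2)),
      coverage = mean(e$ci_low <= g & g <= e$ci_high),
      rejection_rate = mean(e$p_value < 0.05)
    )
  })
  dplyr::bind_rows(rows)
}
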