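# Fixture builders and independent oracles shared across test files.

# Closed-form simple-regression oracle (normal equations), independent of
# the lm-based implementation path.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept,
       residuals = y - intercept - slope * x)
}

# Random aggregated counts fixture with strictly positive counts.
random_counts_fixture <- function(n_states = 4, n_species = 12, seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(state = sprintf("st%02d", seq_len(n_states)),
                        species = sprintf("sp%03d", seq_len(n_species)),
                        stringsAsFactors = FALSE)
    grid$n_ebird <- 1L + stats::rpois(nrow(grid), 50)
    grid$n_inat <- 1L + stats::rpois(nrow(grid), 20)
    tibble::as_tibble(grid)
  })
}

# Random checklist/observation fixture for prevalence and aggregation
# oracles: returns checklists (all passing quality filters) and per-
# checklist species observations.
random_obs_fixture <- function(n_states = 3, n_checklists = 40,
                               n_species = 15, seed = 1) {
  withr::with_seed(seed, {
    total <- n_states * n_checklists
    cl <- tibble::tibble(
      checklist_id = sprintf("cl%04d", seq_len(total)),
      state = rep(sprintf("st%02d", seq_len(n_states)),
                  each = n_checklists),
      protocol = "stationary", complete = TRUE,
      duration_min = 60, distance_km = NA_real_)
    p <- stats::rbeta(n_species, 1, 2)
    rows <- list()
    for (i in seq_len(total)) {
      hit <- which(stats::runif(n_species) < p)
      if (length(hit)) {
        rows[[i]] <- tibble::tibble(
          checklist_id = cl$checklist_id[i],
          species = sprintf("sp%03d", hit),
          count = as.character(1L + stats::rpois(length(hit), 3)))
      }
    }
    list(checklists = cl, ebird_obs = dplyr::bind_rows(rows))
  })
}

# Brute-force set-membership prevalence recount.
brute_prevalence <- function(ebird_obs, checklists) {
  out <- list()
  for (s in unique(checklists$state)) {
    ids <- checklists$checklist_id[checklists$state == s]
    sub <- ebird_obs[ebird_obs$checklist_id %in% ids, ]
    for (sp in unique(sub$species)) {
      n_with <- length(unique(sub$checklist_id[sub$species == sp]))
      out[[paste(s, sp)]] <- tibble::tibble(
        state = s, species = sp, n_ebird = n_with,
        prevalence = n_with / length(ids))
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), state, species)
}

# Minimal single-patch table builder for color tests.
patch_row <- function(species, R, G, B, sex = "male", patch = "crown") {
  tibble::tibble(species = species, sex = sex, patch = patch,
                 R = R, G = G, B = B)
}
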