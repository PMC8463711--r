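# Synthetic observation data with planted state and trait effects.
# Everything downstream (filters, prevalence trimming, the residual
# statistic, the mixed models) is validated against the recorded truth, so
# the pipeline is testable without the multi-hundred-GB real extracts.

#' Configuration for the species-trait generator
#'
#' Defaults sketch a contiguous-US-like passerine-dominated species pool:
#' log10 body mass Normal(1.6, 0.45) (median about 40 g, tails from
#' kinglets to raptors), log10 flock size Normal(0.4, 0.35) truncated at 0
#' (flocks of at least one bird), a Beta(1.2, 1.8) colorfulness target
#' (most species dull, a bright tail), and Red List probabilities
#' (LC, NT, VU, EN) = (0.92, 0.04, 0.03, 0.01) so a handful of endangered
#' species is present to exercise their exclusion.
#'
#' @param n_species Number of species (at least 2).
#' @param body_mass_log10_mean,body_mass_log10_sd Log10-gram scale.
#' @param color_shape1,color_shape2 Beta shapes for the colorfulness target
#'   in \[0, 1\].
#' @param flock_size_log10_mean,flock_size_log10_sd Log10-individual scale.
#' @param iucn_probs Probabilities over (LeastConcern, NearThreatened,
#'   Vulnerable) with an optional Endangered entry; must sum to 1.
#' @param trait_correlation Correlation between log body mass and log flock
#'   size (the joint trait distribution is otherwise independent).
#' @param seed Integer master seed.
#' @return A `trait_gen_config` list.
#' @export
trait_gen_config <- function(n_species,
                             body_mass_log10_mean = 1.6,
                             body_mass_log10_sd = 0.45,
                             color_shape1 = 1.2, color_shape2 = 1.8,
                             flock_size_log10_mean = 0.4,
                             flock_size_log10_sd = 0.35,
                             iucn_probs = c(LeastConcern = 0.92,
                                            NearThreatened = 0.04,
                                            Vulnerable = 0.03,
                                            Endangered = 0.01),
                             trait_correlation = 0,
                             seed = 1L) {
  if (!is.numeric(n_species) || length(n_species) != 1 || n_species < 2) {
    stop("'n_species' must be a single integer >= 2", call. = FALSE)
  }
  assert_number(body_mass_log10_sd, "body_mass_log10_sd", lower = 0)
  assert_number(flock_size_log10_sd, "flock_size_log10_sd", lower = 0)
  assert_number(color_shape1, "color_shape1", lower = 1e-12)
  assert_number(color_shape2, "color_shape2", lower = 1e-12)
  assert_number(trait_correlation, "trait_correlation", -1, 1)
  if (length(iucn_probs) < 3 || length(iucn_probs) > 4 ||
      any(iucn_probs < 0) || abs(sum(iucn_probs) - 1) > 1e-12) {
    stop("'iucn_probs' must be 3 or 4 nonnegative probabilities summing ",
         "to 1", call. = FALSE)
  }
  if (length(iucn_probs) == 3) iucn_probs <- c(iucn_probs, Endangered = 0)
  names(iucn_probs) <- c("LeastConcern", "NearThreatened", "Vulnerable",
                         "Endangered")
  structure(
    list(n_species = as.integer(n_species),
         body_mass_log10_mean = body_mass_log10_mean,
         body_mass_log10_sd = body_mass_log10_sd,
         color_shape1 = color_shape1, color_shape2 = color_shape2,
         flock_size_log10_mean = flock_size_log10_mean,
         flock_size_log10_sd = flock_size_log10_sd,
         iucn_probs = iucn_probs,
         trait_correlation = trait_correlation,
         seed = as.integer(seed)),
    class = "trait_gen_config"
  )
}

# Patch colors interpolate from the brown reference toward white as the
# colorfulness target u rises; both index components (distance from brown,
# relative luminance) are strictly increasing along that segment, so the
# species attaining the largest u attains the largest index.
make_patches <- function(species, u) {
  brown <- brown_reference()
  white <- c(R = 255, G = 255, B = 255)
  grid <- expand.grid(sex = c("male", "female"), patch = PATCH_NAMES,
                      stringsAsFactors = FALSE)
  n_patch <- nrow(grid)
  rows <- lapply(seq_along(species), function(i) {
    # one patch carries the species' target u; the rest sit below it
    frac <- u[i] * stats::runif(n_patch, 0, 0.9)
    frac[sample.int(n_patch, 1)] <- u[i]
    tibble::tibble(
      species = species[i], sex = grid$sex, patch = grid$patch,
      R = round(brown["R"] + frac * (white["R"] - brown["R"]), 2),
      G = round(brown["G"] + frac * (white["G"] - brown["G"]), 2),
      B = round(brown["B"] + frac * (white["B"] - brown["B"]), 2)
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate a synthetic species pool with traits
#'
#' Draws body masses, flock-size targets, IUCN categories, and a set of six
#' plumage patches per sex whose colors are constructed so the computed
#' color index tracks each species' colorfulness target. Deterministic
#' given the config seed.
#'
#' @param cfg A [trait_gen_config()].
#' @return List of class `species_traits`: `species` (tibble with
#'   `species`, `body_mass_g`, `log10_body_mass`, `log10_flock_size`,
#'   `flock_size`, `iucn_category`, `color_target`) and `patches` (long
#'   patch tibble).
#' @export
generate_traits <- function(cfg) {
  stopifnot(inherits(cfg, "trait_gen_config"))
  n <- cfg$n_species
  withr::local_seed(substream_seed(cfg$seed, 1L))
  sp <- sprintf("sp%04d", seq_len(n))
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  rho <- cfg$trait_correlation
  z2 <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  log10_mass <- cfg$body_mass_log10_mean + cfg$body_mass_log10_sd * z[, 1]
  log10_flock <- pmax(0, cfg$flock_size_log10_mean +
                        cfg$flock_size_log10_sd * z2)
  u <- stats::rbeta(n, cfg$color_shape1, cfg$color_shape2)
  iucn <- sample(names(cfg$iucn_probs), n, replace = TRUE,
                 prob = cfg$iucn_probs)
  species <- tibble::tibble(
    species = sp,
    body_mass_g = 10^log10_mass,
    log10_body_mass = log10_mass,
    log10_flock_size = log10_flock,
    flock_size = 10^log10_flock,
    iucn_category = iucn,
    color_target = u
  )
  structure(list(species = species, patches = make_patches(sp, u)),
            class = "species_traits")
}

#' Planted truth for the generative representation model
#'
#' Encodes the generative counterpart of the residual statistic: per state
#' an intercept and a common log10-log10 slope linking unstructured to
#' semi-structured counts, plus per-trait effects (`gamma_*`) on the log10
#' unstructured count and a residual noise standard deviation. The default
#' intercepts center on -2.3 (a roughly 200:1 ratio between the platforms'
#' observation totals, typical of aggregate US data).
#'
#' @param states Character vector of state labels.
#' @param slope_b Common log-log slope (default 1).
#' @param state_intercept_mean,state_intercept_sd Intercept distribution.
#' @param gamma_body,gamma_flock,gamma_color,gamma_iucn Effects of the
#'   centered traits on the log10 unstructured count.
#' @param noise_sd Residual sd on the log10 scale (>= 0).
#' @param seed Integer seed for the intercept draws.
#' @return A `planted_effects` list with a named `state_intercepts` vector.
#' @export
planted_effects <- function(states, slope_b = 1,
                            state_intercept_mean = -2.3,
                            state_intercept_sd = 0.25,
                            gamma_body = 0, gamma_flock = 0,
                            gamma_color = 0, gamma_iucn = 0,
                            noise_sd = 0.1, seed = 1L) {
  assert_number(noise_sd, "noise_sd", lower = 0)
  states <- as.character(states)
  if (!length(states) || anyDuplicated(states)) {
    stop("'states' must be a non-empty set of unique labels", call. = FALSE)
  }
  withr::local_seed(substream_seed(seed, 2L))
  ints <- stats::rnorm(length(states), state_intercept_mean,
                       state_intercept_sd)
  names(ints) <- states
  structure(
    list(slope_b = slope_b, state_intercepts = ints,
         gamma_body = gamma_body, gamma_flock = gamma_flock,
         gamma_color = gamma_color, gamma_iucn = gamma_iucn,
         noise_sd = noise_sd),
    class = "planted_effects"
  )
}

required_trait_cols <- c("species", "log10_body_mass", "color_index",
                         "log10_flock_size", "iucn_score")

# Centered trait contribution; NA traits (e.g. excluded IUCN categories)
# contribute the species-mean, i.e. zero after centering.
centered_or_zero <- function(x) {
  m <- mean(x, na.rm = TRUE)
  out <- x - m
  out[is.na(out)] <- 0
  out
}

#' Generate aggregated paired counts with planted effects
#'
#' Produces, per (state, species), a semi-structured count drawn from a
#' positively skewed (log-normal, truncated at 1) distribution scaled by
#' state effort, and an unstructured count whose expected log10 value is
#' `state_intercept + slope_b * log10(ebird) + sum(gamma * centered trait)`
#' plus Normal noise, rounded to a nonnegative integer. Rows rounded to
#' zero are flagged (`zero_inat`), never dropped; the pre-rounding value is
#' kept in `latent_log10_inat` for diagnostics.
#'
#' @param trait_tbl Trait vector table ([build_trait_table()] output).
#' @param states Character vector of states to simulate.
#' @param effort Named vector: semi-structured checklist effort per state
#'   (positive).
#' @param truth A [planted_effects()] object covering every state.
#' @param seed Integer seed.
#' @param prevalence_meanlog,prevalence_sdlog Log-normal parameters of the
#'   per-species reporting rate (capped at 1); the default gives a skewed
#'   spread of common and scarce species.
#' @param state_noise_sdlog Log-normal spread of state-by-species effort
#'   noise on the semi-structured counts.
#' @return Tibble: `state`, `species`, `n_ebird`, `n_inat`, `zero_inat`,
#'   `latent_log10_inat`.
#' @export
generate_counts_direct <- function(trait_tbl, states, effort, truth,
                                   seed = 1L,
                                   prevalence_meanlog = log(0.08),
                                   prevalence_sdlog = 1,
                                   state_noise_sdlog = 0.6) {
  stopifnot(inherits(truth, "planted_effects"))
  missing_cols <- setdiff(required_trait_cols, names(trait_tbl))
  if (length(missing_cols)) {
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  states <- as.character(states)
  unknown <- setdiff(states, names(truth$state_intercepts))
  if (length(unknown)) {
    stop("no planted intercept for state(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(effort))) names(effort) <- states
  if (any(!states %in% names(effort)) || any(effort[states] <= 0)) {
    stop("'effort' must supply a positive value for every state",
         call. = FALSE)
  }
  num_cols <- setdiff(required_trait_cols, c("species", "iucn_score"))
  if (any(!is.finite(as.matrix(trait_tbl[, num_cols])))) {
    stop("trait columns ", paste(num_cols, collapse = ", "),
         " must be finite", call. = FALSE)
  }

  withr::local_seed(substream_seed(seed, 3L))
  n_sp <- nrow(trait_tbl)
  rate <- pmin(1, stats::rlnorm(n_sp, prevalence_meanlog, prevalence_sdlog))

  x_body <- centered_or_zero(trait_tbl$log10_body_mass)
  x_flock <- centered_or_zero(trait_tbl$log10_flock_size)
  x_color <- centered_or_zero(trait_tbl$color_index)
  x_iucn <- centered_or_zero(trait_tbl$iucn_score)
  trait_term <- truth$gamma_body * x_body + truth$gamma_flock * x_flock +
    truth$gamma_color * x_color + truth$gamma_iucn * x_iucn

  grid <- tidyr::expand_grid(state = states, i = seq_len(n_sp))
  n <- nrow(grid)
  e_noise <- stats::rlnorm(n, 0, state_noise_sdlog)
  n_ebird <- pmax(1, round(effort[grid$state] * rate[grid$i] * e_noise))
  latent <- truth$state_intercepts[grid$state] +
    truth$slope_b * log10(n_ebird) + trait_term[grid$i] +
    stats::rnorm(n, 0, truth$noise_sd)
  n_inat <- pmax(0, round(10^latent))
  tibble::tibble(
    state = grid$state,
    species = trait_tbl$species[grid$i],
    n_ebird = as.integer(n_ebird),
    n_inat = as.integer(n_inat),
    zero_inat = n_inat == 0L,
    latent_log10_inat = unname(latent)
  )
}

#' Configuration for the event-level synthetic bundle
#'
#' Describes a checklist-level simulation: how many checklists per state,
#' which fraction of them violate each quality criterion (the violations
#' are planted disjointly and labeled, so the filter stage has an exact
#' oracle), the rate of present-but-uncounted (`"X"`) records, and the
#' planted representation truth. Default contamination rates are
#' realistic for raw semi-structured exports: 16% incomplete, 6%
#' incidental/historical, 4% over-distance, 3% under- and 2% over-duration.
#'
#' @param states State labels.
#' @param checklists_per_state Checklists simulated in each state.
#' @param traits_cfg A [trait_gen_config()]; defaults to 60 species.
#' @param contamination Named list of rates: `incomplete`, `bad_protocol`,
#'   `too_far`, `too_short`, `too_long` (nonnegative, summing to < 1).
#' @param x_rate Fraction of observation records reported as `"X"`.
#' @param detection_shape1,detection_shape2 Beta parameters of the
#'   per-species detection probability (spread wide so some species fall
#'   under typical prevalence cutoffs).
#' @param truth Optional [planted_effects()]; the default uses intercepts
#'   around -0.5 so unstructured counts are non-degenerate at desk-scale
#'   checklist numbers (see the methods vignette).
#' @param include_boundaries Plant a few retained checklists at exactly
#'   5 km / 5 min / 240 min to pin the closed-interval filter boundaries.
#' @param seed Integer master seed.
#' @return A `bundle_config` list.
#' @export
bundle_config <- function(states = c("CA", "NY", "TX", "FL", "WA"),
                          checklists_per_state = 400,
                          traits_cfg = NULL,
                          contamination = list(incomplete = 0.16,
                                               bad_protocol = 0.06,
                                               too_far = 0.04,
                                               too_short = 0.03,
                                               too_long = 0.02),
                          x_rate = 0.03,
                          detection_shape1 = 0.8, detection_shape2 = 3,
                          truth = NULL,
                          include_boundaries = TRUE,
                          seed = 1L) {
  states <- as.character(states)
  if (is.null(traits_cfg)) {
    traits_cfg <- trait_gen_config(n_species = 60,
                                   seed = substream_seed(seed, 11L))
  }
  rates <- unlist(contamination)
  needed <- c("incomplete", "bad_protocol", "too_far", "too_short",
              "too_long")
  if (!all(needed %in% names(rates))) {
    stop("'contamination' must name rates: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(rates < 0)) {
    stop("contamination rates must be nonnegative", call. = FALSE)
  }
  if (sum(rates) >= 1) {
    stop("contamination rates must sum to < 1", call. = FALSE)
  }
  assert_number(x_rate, "x_rate", 0, 1)
  if (is.null(truth)) {
    truth <- planted_effects(states, state_intercept_mean = -0.5,
                             state_intercept_sd = 0.2, noise_sd = 0.1,
                             seed = substream_seed(seed, 12L))
  }
  stopifnot(inherits(truth, "planted_effects"))
  if (!all(states %in% names(truth$state_intercepts))) {
    stop("'truth' must carry an intercept for every state", call. = FALSE)
  }
  structure(
    list(states = states,
         checklists_per_state = as.integer(checklists_per_state),
         traits_cfg = traits_cfg,
         contamination = as.list(rates[needed]),
         x_rate = x_rate,
         detection_shape1 = detection_shape1,
         detection_shape2 = detection_shape2,
         truth = truth,
         include_boundaries = isTRUE(include_boundaries),
         seed = as.integer(seed)),
    class = "bundle_config"
  )
}

make_checklists <- function(cfg) {
  n_per <- cfg$checklists_per_state
  total <- n_per * length(cfg$states)
  cl <- tibble::tibble(
    checklist_id = sprintf("cl%06d", seq_len(total)),
    state = rep(cfg$states, each = n_per),
    protocol = sample(c("stationary", "traveling"), total, replace = TRUE,
                      prob = c(0.4, 0.6)),
    complete = TRUE,
    duration_min = round(stats::runif(total, 5, 240), 1),
    distance_km = NA_real_
  )
  trav <- cl$protocol == "traveling"
  cl$distance_km[trav] <- round(stats::runif(sum(trav), 0.1, 5), 2)

  # plant disjoint violations; everything else passes by construction
  rates <- unlist(cfg$contamination)
  n_bad <- round(rates * total)
  bad_idx <- sample.int(total, sum(n_bad))
  split_idx <- split(bad_idx, rep(names(n_bad), n_bad))
  labels <- tibble::tibble(
    checklist_id = cl$checklist_id,
    fail_incomplete = FALSE, fail_protocol = FALSE, fail_distance = FALSE,
    fail_duration_short = FALSE, fail_duration_long = FALSE
  )
  i <- split_idx[["incomplete"]]
  cl$complete[i] <- FALSE
  labels$fail_incomplete[i] <- TRUE
  i <- split_idx[["bad_protocol"]]
  cl$protocol[i] <- sample(c("incidental", "historical"), length(i),
                           replace = TRUE)
  labels$fail_protocol[i] <- TRUE
  i <- split_idx[["too_far"]]
  cl$protocol[i] <- "traveling"
  cl$distance_km[i] <- round(stats::runif(length(i), 5.01, 40), 2)
  labels$fail_distance[i] <- TRUE
  i <- split_idx[["too_short"]]
  cl$duration_min[i] <- round(stats::runif(length(i), 0.5, 4.9), 1)
  labels$fail_duration_short[i] <- TRUE
  i <- split_idx[["too_long"]]
  cl$duration_min[i] <- round(stats::runif(length(i), 240.1, 600), 1)
  labels$fail_duration_long[i] <- TRUE

  if (cfg$include_boundaries) {
    good <- which(!(seq_len(total) %in% bad_idx))
    pick <- good[seq_len(min(3, length(good)))]
    if (length(pick) >= 1) cl$duration_min[pick[1]] <- 5
    if (length(pick) >= 2) cl$duration_min[pick[2]] <- 240
    if (length(pick) >= 3) {
      cl$protocol[pick[3]] <- "traveling"
      cl$distance_km[pick[3]] <- 5
    }
  }
  labels$pass <- !(labels$fail_incomplete | labels$fail_protocol |
                     labels$fail_distance | labels$fail_duration_short |
                     labels$fail_duration_long)
  list(checklists = cl, labels = labels)
}

#' Generate an event-level synthetic bundle
#'
#' Builds a full checklist-level dataset: checklists with planted, labeled
#' quality violations; per-checklist species observations with reported
#' counts (occasionally `"X"`); and unstructured occurrence rows generated
#' from the planted representation model applied to the clean (passing)
#' checklist aggregates. The ground truth (labels and planted effects) is
#' retained so every downstream stage has an oracle.
#'
#' @param cfg A [bundle_config()].
#' @return List of class `synthetic_bundle`: `checklists`, `labels`,
#'   `ebird_obs`, `inat_obs`, `traits`, `trait_table`, `truth`, `config`.
#' @export
generate_event_level <- function(cfg) {
  stopifnot(inherits(cfg, "bundle_config"))
  traits <- generate_traits(cfg$traits_cfg)
  withr::local_seed(substream_seed(cfg$seed, 4L))
  made <- make_checklists(cfg)
  cl <- made$checklists
  n_sp <- nrow(traits$species)

  # species detection probabilities, mildly jittered per state
  p_sp <- stats::rbeta(n_sp, cfg$detection_shape1, cfg$detection_shape2)
  jit <- matrix(stats::rnorm(n_sp * length(cfg$states), 0, 0.3),
                nrow = n_sp,
                dimnames = list(traits$species$species, cfg$states))
  p_mat <- stats::plogis(stats::qlogis(pmin(pmax(p_sp, 1e-4), 1 - 1e-4)) +
                           jit)

  # one Bernoulli per (checklist, species), drawn as one matrix
  pm <- p_mat[, cl$state, drop = FALSE]           # n_sp x n_checklists
  hits <- which(matrix(stats::runif(length(pm)), nrow = n_sp) < pm,
                arr.ind = TRUE)
  hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
  obs <- tibble::tibble(
    checklist_id = cl$checklist_id[hits[, 2]],
    species = traits$species$species[hits[, 1]]
  )
  flock_mean <- traits$species$flock_size
  names(flock_mean) <- traits$species$species
  counts <- 1L + stats::rpois(nrow(obs), pmax(0, flock_mean[obs$species] - 1))
  is_x <- stats::runif(nrow(obs)) < cfg$x_rate
  obs$count <- as.character(counts)
  obs$count[is_x] <- "X"

  # derived trait vector: color index from the generated patches, flock
  # size from the generated reported counts (as the pipeline would)
  trait_table <- build_trait_table(traits$species, patches = traits$patches,
                                   ebird_obs = obs)

  # unstructured occurrences from the planted model on clean aggregates
  clean_ids <- made$labels$checklist_id[made$labels$pass]
  clean <- obs[obs$checklist_id %in% clean_ids,
               c("checklist_id", "species")] |>
    dplyr::distinct() |>
    dplyr::inner_join(cl[, c("checklist_id", "state")], by = "checklist_id") |>
    dplyr::count(.data$state, .data$species, name = "n_ebird")
  idx <- match(clean$species, trait_table$species)
  trait_term <- truth_trait_term(cfg$truth, trait_table)[idx]
  latent <- cfg$truth$state_intercepts[clean$state] +
    cfg$truth$slope_b * log10(clean$n_ebird) + trait_term +
    stats::rnorm(nrow(clean), 0, cfg$truth$noise_sd)
  n_inat <- pmax(0, round(10^latent))
  inat_obs <- tibble::tibble(
    state = rep(clean$state, n_inat),
    species = rep(clean$species, n_inat)
  )
  inat_obs$obs_id <- sprintf("inat%07d", seq_len(nrow(inat_obs)))
  inat_obs <- inat_obs[, c("obs_id", "state", "species")]

  structure(
    list(checklists = cl, labels = made$labels, ebird_obs = obs,
         inat_obs = inat_obs, traits = traits, trait_table = trait_table,
         truth = cfg$truth, config = cfg),
    class = "synthetic_bundle"
  )
}

truth_trait_term <- function(truth, trait_tbl) {
  truth$gamma_body * centered_or_zero(trait_tbl$log10_body_mass) +
    truth$gamma_flock * centered_or_zero(trait_tbl$log10_flock_size) +
    truth$gamma_color * centered_or_zero(trait_tbl$color_index) +
    truth$gamma_iucn * centered_or_zero(trait_tbl$iucn_score)
}

#' Write a synthetic bundle to CSV files plus JSON truth
#'
#' Emits `checklists.csv`, `ebird_obs.csv`, `inat_obs.csv`,
#' `species_traits.csv` (wide patch columns matching
#' [read_species_traits()]), `labels.csv`, and `truth.json`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide_patches <- bundle$traits$patches |>
    tidyr::pivot_longer(c("R", "G", "B"), names_to = "channel") |>
    tidyr::unite("col", "sex", "patch", "channel") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  traits_wide <- bundle$traits$species[, c("species", "body_mass_g",
                                           "iucn_category",
                                           "log10_flock_size")] |>
    dplyr::left_join(wide_patches, by = "species")
  paths <- c(
    checklists = file.path(dir, "checklists.csv"),
    ebird_obs = file.path(dir, "ebird_obs.csv"),
    inat_obs = file.path(dir, "inat_obs.csv"),
    species_traits = file.path(dir, "species_traits.csv"),
    labels = file.path(dir, "labels.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(bundle$checklists, paths["checklists"])
  readr::write_csv(bundle$ebird_obs, paths["ebird_obs"])
  readr::write_csv(bundle$inat_obs, paths["inat_obs"])
  readr::write_csv(traits_wide, paths["species_traits"])
  readr::write_csv(bundle$labels, paths["labels"])
  jsonlite::write_json(
    list(slope_b = bundle$truth$slope_b,
         state_intercepts = as.list(bundle$truth$state_intercepts),
         gamma_body = bundle$truth$gamma_body,
         gamma_flock = bundle$truth$gamma_flock,
         gamma_color = bundle$truth$gamma_color,
         gamma_iucn = bundle$truth$gamma_iucn,
         noise_sd = bundle$truth$noise_sd),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
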