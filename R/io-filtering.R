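# Readers for the tabular inputs, checklist quality filtering, per-state
# species prevalence, prevalence trimming, and per-(state, species)
# aggregation of observation counts on both platforms.

CHECKLIST_COLS <- c("checklist_id", "state", "protocol", "complete",
                    "duration_min", "distance_km")

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    warning(what, ": ", nrow(probs), " unparseable cell(s), e.g. row ",
            probs$row[1], " (", probs$expected[1], ")", call. = FALSE)
  }
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0) {
    stop(what, " is empty: ", path, call. = FALSE)
  }
  tbl
}

#' Read a checklist table
#'
#' Expects CSV columns `checklist_id`, `state`, `protocol`, `complete`,
#' `duration_min`, `distance_km`. Missing effort values are preserved as
#' `NA` (never coerced to zero); they are resolved by the quality filters.
#'
#' @param path Path to a CSV file.
#' @return Tibble of checklist records.
#' @export
read_checklists <- function(path) {
  tbl <- read_table_checked(path, CHECKLIST_COLS, "checklist table")
  tbl$complete <- as.logical(tbl$complete)
  tbl$duration_min <- as.numeric(tbl$duration_min)
  tbl$distance_km <- as.numeric(tbl$distance_km)
  if (anyDuplicated(tbl$checklist_id)) {
    stop("checklist_id values must be unique", call. = FALSE)
  }
  tbl
}

#' Read checklist-level species observations
#'
#' Expects CSV columns `checklist_id`, `species`, `count`; `count` may be a
#' number or `"X"` (present, not counted) and is kept as character.
#'
#' @inheritParams read_checklists
#' @return Tibble of observation records.
#' @export
read_ebird_obs <- function(path) {
  tbl <- read_table_checked(path, c("checklist_id", "species", "count"),
                            "checklist observation table")
  tbl$count <- as.character(tbl$count)
  tbl
}

#' Read occurrence records from the unstructured platform
#'
#' Expects CSV columns `obs_id`, `state`, `species`; one row is one
#' occurrence (a single unique sighting of a species).
#'
#' @inheritParams read_checklists
#' @return Tibble of occurrence records.
#' @export
read_inat_obs <- function(path) {
  read_table_checked(path, c("obs_id", "state", "species"),
                     "occurrence table")
}

#' Read a wide species-trait table
#'
#' Expects `species`, `body_mass_g`, `iucn_category` plus optional plumage
#' patch columns named `<sex>_<patch>_<channel>` (e.g. `male_crown_R`) and
#' an optional `log10_flock_size`. Patch columns are reshaped into the long
#' patch format used by the color functions.
#'
#' @inheritParams read_checklists
#' @return List with `species` (tibble) and `patches` (long tibble, possibly
#'   empty).
#' @export
read_species_traits <- function(path) {
  tbl <- read_table_checked(path, c("species", "body_mass_g",
                                    "iucn_category"), "species trait table")
  patch_rx <- paste0("^(male|female)_(", paste(PATCH_NAMES, collapse = "|"),
                     ")_(R|G|B)$")
  patch_cols <- grep(patch_rx, names(tbl), value = TRUE)
  patches <- tibble::tibble(species = character(), sex = character(),
                            patch = character(), R = double(),
                            G = double(), B = double())
  if (length(patch_cols)) {
    patches <- tbl[, c("species", patch_cols)] |>
      tidyr::pivot_longer(-"species", names_to = c("sex", "patch", "channel"),
                          names_pattern = "^(male|female)_(.*)_(R|G|B)$") |>
      tidyr::pivot_wider(names_from = "channel", values_from = "value") |>
      dplyr::filter(!is.na(.data$R) & !is.na(.data$G) & !is.na(.data$B))
  }
  keep <- intersect(c("species", "body_mass_g", "iucn_category",
                      "log10_flock_size"), names(tbl))
  list(species = tbl[, keep], patches = patches)
}

#' Checklist quality-filter configuration
#'
#' Defaults mirror standard semi-structured quality control: complete
#' checklists only, no incidental or historical protocols, travel distance
#' of at most 5 km, and duration between 5 and 240 minutes. The boundaries
#' are inclusive (exactly 5 km, 5 min or 240 min is retained) because the
#' exclusions are stated as strict inequalities (`> 5 km`, `< 5 min`,
#' `> 240 min`).
#'
#' @param max_distance_km,min_duration_min,max_duration_min Effort bounds.
#' @param require_complete Keep only complete checklists.
#' @param exclude_protocols Protocol labels removed outright.
#' @param prevalence_cutoff Per-state prevalence below which a species is
#'   trimmed (strict `<`); see [trim_species()].
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_distance_km = 5, min_duration_min = 5,
                          max_duration_min = 240, require_complete = TRUE,
                          exclude_protocols = c("incidental", "historical"),
                          prevalence_cutoff = 0.01) {
  assert_number(max_distance_km, "max_distance_km", lower = 0)
  assert_number(min_duration_min, "min_duration_min", lower = 0)
  assert_number(max_duration_min, "max_duration_min", lower = 0)
  if (min_duration_min >= max_duration_min) {
    stop("'min_duration_min' must be below 'max_duration_min'",
         call. = FALSE)
  }
  assert_number(prevalence_cutoff, "prevalence_cutoff", 0, 1)
  structure(
    list(max_distance_km = max_distance_km,
         min_duration_min = min_duration_min,
         max_duration_min = max_duration_min,
         require_complete = isTRUE(require_complete),
         exclude_protocols = as.character(exclude_protocols),
         prevalence_cutoff = prevalence_cutoff),
    class = "filter_config"
  )
}

#' Apply checklist quality filters
#'
#' Retains checklists that are complete (if required), use an allowed
#' protocol, travelled at most `max_distance_km`, and lasted between
#' `min_duration_min` and `max_duration_min` inclusive. A missing distance
#' is treated as 0 km for stationary checklists (stationary implies no
#' travel) and fails the distance criterion otherwise; a missing duration
#' always fails the duration criterion.
#'
#' The report counts removals once per violated criterion, so criterion
#' counts can exceed the number of removed checklists; the retained +
#' removed split always reconciles with the input exactly.
#'
#' @param checklists Checklist tibble (see [read_checklists()]).
#' @param cfg A [filter_config()].
#' @return List with `checklists` (retained rows) and `report` (counts per
#'   criterion, input/retained/removed totals).
#' @export
filter_checklists <- function(checklists, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  missing <- setdiff(CHECKLIST_COLS, names(checklists))
  if (length(missing)) {
    stop("checklist table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dist <- checklists$distance_km
  dist[is.na(dist) & checklists$protocol == "stationary"] <- 0
  dur <- checklists$duration_min

  fail_incomplete <- cfg$require_complete &
    (is.na(checklists$complete) | !checklists$complete)
  fail_protocol <- checklists$protocol %in% cfg$exclude_protocols
  fail_distance <- !is.na(dist) & dist > cfg$max_distance_km
  fail_distance_missing <- is.na(dist)
  fail_duration_short <- !is.na(dur) & dur < cfg$min_duration_min
  fail_duration_long <- !is.na(dur) & dur > cfg$max_duration_min
  fail_duration_missing <- is.na(dur)

  fail_any <- fail_incomplete | fail_protocol | fail_distance |
    fail_distance_missing | fail_duration_short | fail_duration_long |
    fail_duration_missing

  report <- list(
    n_input = nrow(checklists),
    n_retained = sum(!fail_any),
    n_removed = sum(fail_any),
    removed_by = c(
      incomplete = sum(fail_incomplete),
      protocol = sum(fail_protocol),
      distance = sum(fail_distance),
      distance_missing = sum(fail_distance_missing),
      duration_short = sum(fail_duration_short),
      duration_long = sum(fail_duration_long),
      duration_missing = sum(fail_duration_missing)
    )
  )
  list(checklists = checklists[!fail_any, , drop = FALSE], report = report)
}

#' Per-state species prevalence
#'
#' Prevalence of a species in a state is the fraction of retained checklists
#' in that state on which the species appears. Duplicate species rows within
#' one checklist count once; observations referencing checklists absent from
#' the retained set are dropped (their count is attached as the
#' `n_unmatched` attribute).
#'
#' @param ebird_obs Observation tibble (`checklist_id`, `species`, ...).
#' @param checklists Retained checklist tibble (post-filter).
#' @return Tibble with `state`, `species`, `n_ebird` (distinct checklists
#'   containing the species) and `prevalence`.
#' @export
compute_prevalence <- function(ebird_obs, checklists) {
  state_totals <- dplyr::count(checklists, .data$state,
                               name = "n_checklists")
  obs <- dplyr::distinct(ebird_obs[, c("checklist_id", "species")])
  matched <- dplyr::inner_join(
    obs, checklists[, c("checklist_id", "state")], by = "checklist_id")
  n_unmatched <- nrow(obs) - nrow(matched)
  out <- matched |>
    dplyr::count(.data$state, .data$species, name = "n_ebird") |>
    dplyr::left_join(state_totals, by = "state") |>
    dplyr::mutate(prevalence = .data$n_ebird / .data$n_checklists) |>
    dplyr::select(-"n_checklists")
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Trim species below a prevalence cutoff
#'
#' Removes, per state, species present on fewer than `cutoff` of that
#' state's retained checklists. The inequality is strict (`prevalence <
#' cutoff` is removed), so a species exactly at the cutoff survives; a
#' cutoff of 0 removes nothing that has at least one record. A species may
#' survive in one state and be trimmed in another.
#'
#' @param prevalence Output of [compute_prevalence()].
#' @param cutoff Fraction in \[0, 1\].
#' @return The surviving rows of `prevalence`.
#' @export
trim_species <- function(prevalence, cutoff = 0.01) {
  assert_number(cutoff, "cutoff", 0, 1)
  prevalence[prevalence$prevalence >= cutoff, , drop = FALSE]
}

#' Aggregate per-(state, species) observation counts
#'
#' For the surviving (state, species) pairs, counts one observation per
#' unique (checklist, species) record on the semi-structured platform and
#' one per occurrence row on the unstructured platform. Pairs with zero
#' unstructured observations are kept with `n_inat = 0`; their handling is
#' decided by the representation stage's zero policy.
#'
#' @param ebird_obs Observation tibble.
#' @param inat_obs Occurrence tibble (`state`, `species`).
#' @param checklists Retained checklist tibble.
#' @param retained Surviving rows from [trim_species()].
#' @return Tibble with `state`, `species`, `n_ebird`, `n_inat`,
#'   `prevalence`.
#' @export
aggregate_counts <- function(ebird_obs, inat_obs, checklists, retained) {
  keys <- retained[, c("state", "species", "prevalence")]
  ebird <- ebird_obs[, c("checklist_id", "species")] |>
    dplyr::distinct() |>
    dplyr::inner_join(checklists[, c("checklist_id", "state")],
                      by = "checklist_id") |>
    dplyr::count(.data$state, .data$species, name = "n_ebird")
  inat <- dplyr::count(inat_obs, .data$state, .data$species, name = "n_inat")
  out <- keys |>
    dplyr::left_join(ebird, by = c("state", "species")) |>
    dplyr::left_join(inat, by = c("state", "species"))
  out$n_ebird[is.na(out$n_ebird)] <- 0L
  out$n_inat[is.na(out$n_inat)] <- 0L
  out[, c("state", "species", "n_ebird", "n_inat", "prevalence")]
}
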