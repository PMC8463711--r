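# The core representation statistic: per-state ordinary least squares of
# log10 unstructured (iNaturalist-like) counts on log10 semi-structured
# (eBird-like) counts. The residual is the per-(state, species) over/under-
# representation score: positive = over-represented in the unstructured
# platform.

#' Fit the log-log representation model for one state
#'
#' Ordinary least squares of `log10(n_inat)` on `log10(n_ebird)` over the
#' species of a single state. The residual (observed minus fitted) is the
#' representation score: a species above the state's line is
#' over-represented on the unstructured platform.
#'
#' Zero counts cannot enter a log model; `zero_policy = "drop"` excludes
#' pairs with a zero on either platform (counted in `n_zero_dropped`),
#' `"add_one"` uses `log10(n + 1)` on both axes instead.
#'
#' @param counts Tibble with `species`, `n_ebird`, `n_inat` for one state
#'   (a `state` column, if present, must be constant).
#' @param zero_policy `"drop"` (default) or `"add_one"`.
#' @param min_species Minimum usable species for a reported fit (default 3,
#'   keeping residual degrees of freedom positive).
#' @return A `state_fit` list: `state`, `intercept`, `slope`, `r_squared`,
#'   `n_species`, `n_zero_dropped`, and `residuals` (named by species);
#'   `NULL` (with a warning) when fewer than `min_species` pairs are usable.
#' @export
fit_state_loglog <- function(counts, zero_policy = c("drop", "add_one"),
                             min_species = 3) {
  zero_policy <- match.arg(zero_policy)
  state <- if ("state" %in% names(counts)) {
    u <- unique(counts$state)
    if (length(u) > 1) stop("counts span more than one state", call. = FALSE)
    u
  } else NA_character_

  n_zero <- 0L
  if (zero_policy == "drop") {
    usable <- counts$n_ebird > 0 & counts$n_inat > 0
    n_zero <- sum(!usable)
    counts <- counts[usable, , drop = FALSE]
    x <- log10(counts$n_ebird)
    y <- log10(counts$n_inat)
  } else {
    x <- log10(counts$n_ebird + 1)
    y <- log10(counts$n_inat + 1)
  }
  if (length(x) < min_species) {
    warning("state ", state, " skipped: only ", length(x),
            " usable species (need ", min_species, ")", call. = FALSE)
    return(NULL)
  }
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  names(res) <- counts$species
  r2 <- if (stats::var(y) > 0) summary(fit)$r.squared else NA_real_
  structure(
    list(state = state,
         intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         r_squared = r2,
         n_species = length(x),
         n_zero_dropped = n_zero,
         residuals = res),
    class = "state_fit"
  )
}

#' Build the residual table across all states
#'
#' Repeats the log-log fit separately for each state and stacks the
#' residuals into one table. A species occurring in several states appears
#' once per state (downstream models absorb the replication with a random
#' intercept per state). States with too few usable species are skipped and
#' listed in the `skipped_states` attribute; the per-state fits are attached
#' as the `fits` attribute.
#'
#' @param counts Aggregated counts: `state`, `species`, `n_ebird`, `n_inat`.
#' @inheritParams fit_state_loglog
#' @return Tibble with `state`, `species`, `residual`, `n_ebird`, `n_inat`.
#' @export
build_residual_table <- function(counts, zero_policy = c("drop", "add_one"),
                                 min_species = 3) {
  zero_policy <- match.arg(zero_policy)
  states <- unique(counts$state)
  fits <- list()
  skipped <- character()
  rows <- list()
  for (s in states) {
    sub <- counts[counts$state == s, , drop = FALSE]
    fit <- fit_state_loglog(sub, zero_policy = zero_policy,
                            min_species = min_species)
    if (is.null(fit)) {
      skipped <- c(skipped, s)
      next
    }
    fits[[s]] <- fit
    sub <- sub[match(names(fit$residuals), sub$species), , drop = FALSE]
    rows[[s]] <- tibble::tibble(
      state = s, species = sub$species,
      residual = unname(fit$residuals),
      n_ebird = sub$n_ebird, n_inat = sub$n_inat
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(state = character(), species = character(),
                          residual = double(), n_ebird = integer(),
                          n_inat = integer())
  }
  attr(out, "fits") <- fits
  attr(out, "skipped_states") <- skipped
  out
}

#' Platform correlation summaries
#'
#' Two descriptive checks of how tightly the platforms track each other:
#' at the state level, the R-squared between (log10) state checklist totals
#' and (log10) state occurrence totals; at the species level, the R-squared
#' between (log10) species totals pooled across states on the two
#' platforms. Either summary is omitted (`NULL`) with fewer than 3 points.
#'
#' @param counts Aggregated counts (`state`, `species`, `n_ebird`,
#'   `n_inat`).
#' @param checklist_totals Optional tibble `state`, `n_checklists`; without
#'   it the state-level summary is omitted.
#' @return List with `state_level` and `species_level`, each `NULL` or a
#'   list of `r_squared`, `slope`, `n`.
#' @export
summarize_correlations <- function(counts, checklist_totals = NULL) {
  loglog_r2 <- function(x, y) {
    keep <- x > 0 & y > 0
    if (sum(keep) < 3) return(NULL)
    fit <- stats::lm(log10(y[keep]) ~ log10(x[keep]))
    list(r_squared = summary(fit)$r.squared,
         slope = unname(stats::coef(fit)[2]),
         n = sum(keep))
  }
  state_level <- NULL
  if (!is.null(checklist_totals)) {
    st <- counts |>
      dplyr::group_by(.data$state) |>
      dplyr::summarise(inat_total = sum(.data$n_inat), .groups = "drop") |>
      dplyr::inner_join(checklist_totals, by = "state")
    state_level <- loglog_r2(st$n_checklists, st$inat_total)
  }
  sp <- counts |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(ebird_total = sum(.data$n_ebird),
                     inat_total = sum(.data$n_inat), .groups = "drop")
  species_level <- loglog_r2(sp$ebird_total, sp$inat_total)
  list(state_level = state_level, species_level = species_level)
}
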