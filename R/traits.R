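# Construction of the four species-level predictors: log10 body mass,
# plumage color index, mean flock size, and ordinal IUCN score.

PATCH_NAMES <- c("upper_breast", "lower_breast", "crown",
                 "forehead", "nape", "throat")

#' Default brown reference color
#'
#' The colorfulness component of the color index is the maximum Euclidean
#' distance of any plumage patch from a brown reference. The standard brown
#' is (R = 102, G = 68, B = 0); `printed = TRUE` returns the variant with the
#' G and B channels transposed, which some sources list.
#'
#' @param printed logical; return the transposed-channel variant.
#' @return Named numeric vector with elements `R`, `G`, `B`.
#' @export
brown_reference <- function(printed = FALSE) {
  if (printed) c(R = 102, G = 0, B = 68) else c(R = 102, G = 68, B = 0)
}

check_patches <- function(patches) {
  needed <- c("species", "sex", "patch", "R", "G", "B")
  missing <- setdiff(needed, names(patches))
  if (length(missing)) {
    stop("patch table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chan <- c(patches$R, patches$G, patches$B)
  if (any(!is.finite(chan)) || any(chan < 0) || any(chan > 255)) {
    stop("RGB channels must be finite and within [0, 255]", call. = FALSE)
  }
  invisible(patches)
}

rgb_to_lab <- function(rgb255) {
  grDevices::convertColor(rgb255 / 255, from = "sRGB", to = "Lab")
}

#' Distance from brown (colorfulness component)
#'
#' For each species, the maximum Euclidean distance in RGB color space
#' between any of its plumage patches (both sexes pooled) and a brown
#' reference color. Larger values indicate plumage further from dull brown.
#'
#' @param patches Long patch table: columns `species`, `sex`, `patch`,
#'   `R`, `G`, `B` (channels in 0--255).
#' @param reference Reference color, named `R`/`G`/`B`; see
#'   [brown_reference()].
#' @param space `"rgb"` computes the distance directly on RGB channels;
#'   `"lab"` converts both patch and reference to CIE Lab (sRGB, D65) first.
#' @return Tibble with columns `species`, `distance_from_brown`.
#' @export
distance_from_brown <- function(patches, reference = brown_reference(),
                                space = c("rgb", "lab")) {
  space <- match.arg(space)
  check_patches(patches)
  if (nrow(patches) == 0) stop("no patches supplied", call. = FALSE)
  m <- as.matrix(patches[, c("R", "G", "B")])
  ref <- as.numeric(reference[c("R", "G", "B")])
  if (space == "lab") {
    m <- rgb_to_lab(m)
    ref <- as.numeric(rgb_to_lab(matrix(ref, nrow = 1)))
  }
  d <- sqrt((m[, 1] - ref[1])^2 + (m[, 2] - ref[2])^2 + (m[, 3] - ref[3])^2)
  tibble::tibble(species = patches$species, d = d) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(distance_from_brown = max(.data$d), .groups = "drop")
}

#' Relative luminance (brightness component)
#'
#' For each species, the maximum relative luminance
#' `0.2126 R + 0.7152 G + 0.0722 B` over all patches of both sexes.
#' On 0--255 channels the result lies in \[0, 255\].
#'
#' @inheritParams distance_from_brown
#' @return Tibble with columns `species`, `relative_luminance`.
#' @export
relative_luminance <- function(patches) {
  check_patches(patches)
  if (nrow(patches) == 0) stop("no patches supplied", call. = FALSE)
  lum <- 0.2126 * patches$R + 0.7152 * patches$G + 0.0722 * patches$B
  tibble::tibble(species = patches$species, lum = lum) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(relative_luminance = max(.data$lum), .groups = "drop")
}

#' Composite color index
#'
#' Combines the distance-from-brown and relative-luminance components into a
#' single colorfulness/brightness score per species. Each component is
#' min-max scaled to \[0, 1\] over the supplied species set, the two are
#' combined as a weighted mean, and the combination is min-max rescaled to
#' \[0, 1\]. Both endpoints are therefore always attained by some species.
#'
#' The index is relative to the species set: adding or removing species
#' changes the scaling (but never the underlying components).
#'
#' @inheritParams distance_from_brown
#' @param weights Length-2 nonnegative weights for (distance, luminance);
#'   equal weights by default.
#' @return Tibble with columns `species`, `distance_from_brown`,
#'   `relative_luminance`, `color_index`.
#' @export
color_index <- function(patches, reference = brown_reference(),
                        weights = c(0.5, 0.5), space = c("rgb", "lab")) {
  space <- match.arg(space)
  if (length(weights) != 2 || any(weights < 0) || sum(weights) <= 0) {
    stop("'weights' must be two nonnegative numbers with positive sum",
         call. = FALSE)
  }
  dist <- distance_from_brown(patches, reference = reference, space = space)
  lum <- relative_luminance(patches)
  comp <- dplyr::inner_join(dist, lum, by = "species")
  if (nrow(comp) < 2) {
    stop("color index needs at least 2 species to define the scaling",
         call. = FALSE)
  }
  w <- weights / sum(weights)
  d_s <- minmax_scale(comp$distance_from_brown, "distance_from_brown")
  l_s <- minmax_scale(comp$relative_luminance, "relative_luminance")
  combined <- w[1] * d_s + w[2] * l_s
  comp$color_index <- minmax_scale(combined, "combined color components")
  comp
}

#' Mean flock size per species
#'
#' The average number of reported individuals over all checklists on which a
#' species was reported, pooled across all states ("across all data").
#' Present-but-uncounted records (count `"X"`) are excluded from both the
#' numerator and the denominator; a species with only `"X"` records gets a
#' missing flock size.
#'
#' @param ebird_obs Checklist observation table with columns `species` and
#'   `count` (integer-like strings, possibly `"X"`).
#' @return Tibble with columns `species`, `flock_size`, `n_counted`, `n_x`.
#' @export
flock_size <- function(ebird_obs) {
  if (!all(c("species", "count") %in% names(ebird_obs))) {
    stop("observation table needs columns 'species' and 'count'",
         call. = FALSE)
  }
  cnt <- as.character(ebird_obs$count)
  is_x <- !is.na(cnt) & toupper(trimws(cnt)) == "X"
  num <- suppressWarnings(as.numeric(cnt))
  num[is_x] <- NA_real_
  tibble::tibble(species = ebird_obs$species, n = num, x = is_x) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      flock_size = if (any(!is.na(.data$n))) mean(.data$n, na.rm = TRUE)
                   else NA_real_,
      n_counted = sum(!is.na(.data$n)),
      n_x = sum(.data$x),
      .groups = "drop"
    )
}

IUCN_SCORES <- c(leastconcern = 2, vulnerable = 1, nearthreatened = 0)
IUCN_EXCLUDED <- c("endangered", "criticallyendangered",
                   "extinctinthewild", "extinct")

#' Ordinal IUCN score
#'
#' Encodes Red List categories as an ordinal commonness proxy with Least
#' Concern highest and Near Threatened lowest: LC = 2, VU = 1, NT = 0.
#' Endangered and rarer categories return `NA`, marking the species for
#' exclusion from IUCN-bearing models (too few such species for inference).
#'
#' @param category Character vector of category labels; tolerant of
#'   spacing/case ("Least Concern", "least_concern", "LC", ...).
#' @return Numeric vector of scores, `NA` for excluded categories.
#' @export
encode_iucn <- function(category) {
  key <- gsub("[^a-z]", "", tolower(as.character(category)))
  key[key == "lc"] <- "leastconcern"
  key[key == "nt"] <- "nearthreatened"
  key[key == "vu"] <- "vulnerable"
  key[key == "en"] <- "endangered"
  key[key == "cr"] <- "criticallyendangered"
  out <- rep(NA_real_, length(key))
  known <- key %in% c(names(IUCN_SCORES), IUCN_EXCLUDED)
  bad <- !known & !is.na(category)
  if (any(bad)) {
    stop(
      "unrecognized IUCN categor", if (sum(bad) > 1) "ies: " else "y: ",
      paste(unique(category[bad]), collapse = ", "),
      ". Accepted: Least Concern, Near Threatened, Vulnerable, Endangered, ",
      "Critically Endangered, Extinct in the Wild, Extinct.",
      call. = FALSE
    )
  }
  hit <- key %in% names(IUCN_SCORES)
  out[hit] <- unname(IUCN_SCORES[key[hit]])
  out
}

#' Assemble the species trait vector table
#'
#' Joins the four model predictors into one row per species:
#' `log10_body_mass`, `color_index`, `log10_flock_size`, `iucn_score`.
#' Any predictor that cannot be computed for a species is `NA`; completeness
#' is resolved per model downstream.
#'
#' @param species_tbl Tibble with `species`, `body_mass_g`, `iucn_category`,
#'   and optionally `log10_flock_size` (used when `ebird_obs` is `NULL`).
#' @param patches Optional long patch table for the color index.
#' @param ebird_obs Optional filtered observation table; when given, flock
#'   size is estimated from reported counts via [flock_size()].
#' @param reference,weights,space Passed to [color_index()].
#' @return Tibble with one row per species and the four predictors.
#' @export
build_trait_table <- function(species_tbl, patches = NULL, ebird_obs = NULL,
                              reference = brown_reference(),
                              weights = c(0.5, 0.5), space = "rgb") {
  if (!all(c("species", "body_mass_g", "iucn_category") %in%
           names(species_tbl))) {
    stop("species table needs 'species', 'body_mass_g', 'iucn_category'",
         call. = FALSE)
  }
  if (any(!is.na(species_tbl$body_mass_g) & species_tbl$body_mass_g <= 0)) {
    stop("body mass must be positive (grams)", call. = FALSE)
  }
  out <- tibble::tibble(
    species = species_tbl$species,
    log10_body_mass = log10(species_tbl$body_mass_g),
    iucn_score = encode_iucn(species_tbl$iucn_category)
  )
  if (!is.null(patches) && nrow(patches) > 0) {
    ci <- color_index(patches, reference = reference, weights = weights,
                      space = space)
    out <- dplyr::left_join(out, ci[, c("species", "color_index")],
                            by = "species")
  } else {
    out$color_index <- NA_real_
  }
  if (!is.null(ebird_obs)) {
    fs <- flock_size(ebird_obs)
    out <- dplyr::left_join(out, fs[, c("species", "flock_size")],
                            by = "species")
    out$log10_flock_size <- log10(out$flock_size)
    out$flock_size <- NULL
  } else if ("log10_flock_size" %in% names(species_tbl)) {
    out <- dplyr::left_join(
      out, species_tbl[, c("species", "log10_flock_size")], by = "species")
  } else {
    out$log10_flock_size <- NA_real_
  }
  out[, c("species", "log10_body_mass", "color_index",
          "log10_flock_size", "iucn_score")]
}
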