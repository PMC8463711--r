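# End-to-end orchestration: one config (list or YAML) in, tables, model
# reports and a reconciling manifest out. Works on synthetic bundles or on
# user-supplied CSV files.

default_run_config <- function() {
  list(
    mode = "synthetic",
    seed = 1L,
    output_dir = NULL,
    synthetic = list(
      states = c("CA", "NY", "TX", "FL", "WA"),
      checklists_per_state = 400L,
      n_species = 60L,
      gamma_body = 0, gamma_flock = 0, gamma_color = 0, gamma_iucn = 0,
      noise_sd = 0.1,
      state_intercept_mean = -0.5, state_intercept_sd = 0.2
    ),
    files = list(checklists = NULL, ebird_obs = NULL, inat_obs = NULL,
                 species_traits = NULL),
    filter = list(max_distance_km = 5, min_duration_min = 5,
                  max_duration_min = 240, require_complete = TRUE,
                  exclude_protocols = c("incidental", "historical")),
    prevalence_cutoffs = 0.01,
    zero_policy = "drop",
    color = list(reference = "standard", space = "rgb",
                 weights = c(0.5, 0.5)),
    model = list(estimation = "REML", ci_level = 0.95)
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline run configuration
#'
#' Checks a config list (or YAML file) against the known keys and value
#' ranges. All problems are collected and returned together rather than
#' failing at the first.
#'
#' @param config A named list, or the path to a YAML file.
#' @return Character vector of problems; empty when the config is valid.
#'   The merged (defaults-filled) config is attached as the `config`
#'   attribute.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      return("config file does not exist")
    }
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown config key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  cfg <- merge_config(defaults, config[setdiff(names(config), unknown)])
  if (!cfg$mode %in% c("synthetic", "files")) {
    problems <- c(problems, "mode must be 'synthetic' or 'files'")
  }
  cuts <- cfg$prevalence_cutoffs
  if (!is.numeric(cuts) || !length(cuts) || any(cuts < 0 | cuts > 1)) {
    problems <- c(problems,
                  "prevalence_cutoffs must be fractions in [0, 1]")
  }
  if (!cfg$zero_policy %in% c("drop", "add_one")) {
    problems <- c(problems, "zero_policy must be 'drop' or 'add_one'")
  }
  if (!cfg$color$reference %in% c("standard", "printed")) {
    problems <- c(problems, "color$reference must be 'standard' or 'printed'")
  }
  if (!cfg$color$space %in% c("rgb", "lab")) {
    problems <- c(problems, "color$space must be 'rgb' or 'lab'")
  }
  if (!cfg$model$estimation %in% c("REML", "ML")) {
    problems <- c(problems, "model$estimation must be 'REML' or 'ML'")
  }
  if (cfg$mode == "files") {
    for (f in c("checklists", "ebird_obs", "inat_obs", "species_traits")) {
      p <- cfg$files[[f]]
      if (is.null(p)) {
        problems <- c(problems, paste0("files$", f, " is required in files mode"))
      } else if (!file.exists(p)) {
        problems <- c(problems, paste0("files$", f, " does not exist: ", p))
      }
    }
  }
  f <- cfg$filter
  if (f$min_duration_min >= f$max_duration_min) {
    problems <- c(problems,
                  "filter$min_duration_min must be below max_duration_min")
  }
  attr(problems, "config") <- cfg
  problems
}

cutoff_tag <- function(cutoff) {
  paste0("c", gsub("\\.", "p", format(cutoff, trim = TRUE)))
}

model_result_json <- function(res) {
  list(fixed_effects = res$fixed_effects,
       random_intercept_variance = res$random_intercept_variance,
       residual_variance = res$residual_variance,
       n_rows = res$n_rows, n_species = res$n_species,
       n_states = res$n_states, converged = res$converged,
       singular = res$singular, method = res$method,
       ci_method = res$ci_method)
}

#' Run the full pipeline
#'
#' Orchestrates one end-to-end run: acquire data (generate a synthetic
#' bundle, or read the four CSV inputs), filter checklists, compute
#' prevalence, trim species at each requested cutoff, aggregate counts,
#' compute the representation residuals, build traits, fit the global and
#' single-trait mixed models, and write all artifacts plus a manifest whose
#' stage counts reconcile. In synthetic mode the planted truth is compared
#' with the recovered global estimates.
#'
#' Outputs carry no timestamps, so two runs with the same config and seed
#' produce byte-identical artifacts.
#'
#' @param config Named list or YAML path; see [validate_run_config()].
#' @param output_dir Overrides `config$output_dir`.
#' @return The manifest, invisibly; artifacts are written to the output
#'   directory.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  problems <- validate_run_config(config)
  if (length(problems)) {
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg <- attr(problems, "config")
  out_dir <- output_dir %||% cfg$output_dir
  if (is.null(out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (cfg$mode == "synthetic") {
    syn <- cfg$synthetic
    bcfg <- bundle_config(
      states = syn$states,
      checklists_per_state = syn$checklists_per_state,
      traits_cfg = trait_gen_config(syn$n_species,
                                    seed = substream_seed(cfg$seed, 11L)),
      truth = planted_effects(
        syn$states, gamma_body = syn$gamma_body,
        gamma_flock = syn$gamma_flock, gamma_color = syn$gamma_color,
        gamma_iucn = syn$gamma_iucn, noise_sd = syn$noise_sd,
        state_intercept_mean = syn$state_intercept_mean,
        state_intercept_sd = syn$state_intercept_sd,
        seed = substream_seed(cfg$seed, 12L)),
      seed = cfg$seed)
    bundle <- generate_event_level(bcfg)
    write_bundle(bundle, file.path(out_dir, "inputs"))
    checklists <- bundle$checklists
    ebird_obs <- bundle$ebird_obs
    inat_obs <- bundle$inat_obs
    species_tbl <- bundle$traits$species
    patches <- bundle$traits$patches
    truth <- bundle$truth
  } else {
    checklists <- read_checklists(cfg$files$checklists)
    ebird_obs <- read_ebird_obs(cfg$files$ebird_obs)
    inat_obs <- read_inat_obs(cfg$files$inat_obs)
    tr <- read_species_traits(cfg$files$species_traits)
    species_tbl <- tr$species
    patches <- tr$patches
  }

  fcfg <- filter_config(
    max_distance_km = cfg$filter$max_distance_km,
    min_duration_min = cfg$filter$min_duration_min,
    max_duration_min = cfg$filter$max_duration_min,
    require_complete = cfg$filter$require_complete,
    exclude_protocols = cfg$filter$exclude_protocols,
    prevalence_cutoff = cfg$prevalence_cutoffs[1])
  filtered <- filter_checklists(checklists, fcfg)
  retained_cl <- filtered$checklists
  obs_retained <- dplyr::semi_join(ebird_obs, retained_cl,
                                   by = "checklist_id")
  prevalence <- compute_prevalence(ebird_obs, retained_cl)

  reference <- brown_reference(printed = cfg$color$reference == "printed")
  trait_tbl <- build_trait_table(
    species_tbl, patches = if (nrow(patches)) patches else NULL,
    ebird_obs = obs_retained, reference = reference,
    weights = cfg$color$weights, space = cfg$color$space)
  readr::write_csv(trait_tbl, file.path(out_dir, "traits.csv"))

  mspec <- model_spec(estimation = cfg$model$estimation,
                      ci_level = cfg$model$ci_level)
  checklist_totals <- dplyr::count(retained_cl, .data$state,
                                   name = "n_checklists")

  per_cutoff <- list()
  correlations <- NULL
  for (cutoff in cfg$prevalence_cutoffs) {
    tag <- cutoff_tag(cutoff)
    retained_sp <- trim_species(prevalence, cutoff)
    counts <- aggregate_counts(ebird_obs, inat_obs, retained_cl,
                               retained_sp)
    resid_tbl <- suppressWarnings(
      build_residual_table(counts, zero_policy = cfg$zero_policy))
    fits <- fit_all(resid_tbl, trait_tbl, mspec)
    readr::write_csv(counts, file.path(out_dir,
                                       paste0("counts_", tag, ".csv")))
    readr::write_csv(resid_tbl, file.path(out_dir,
                                          paste0("residuals_", tag, ".csv")))
    jsonlite::write_json(
      c(list(global = model_result_json(fits$global)),
        lapply(fits$per_trait, model_result_json)),
      file.path(out_dir, paste0("models_", tag, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (cutoff == cfg$prevalence_cutoffs[1]) {
      correlations <- summarize_correlations(counts, checklist_totals)
      jsonlite::write_json(correlations,
                           file.path(out_dir, "correlations.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    per_cutoff[[tag]] <- list(
      cutoff = cutoff,
      n_species_retained = length(unique(retained_sp$species)),
      n_pairs = nrow(counts),
      n_residual_rows = nrow(resid_tbl),
      skipped_states = attr(resid_tbl, "skipped_states"),
      global_n_rows = fits$global$n_rows,
      global_method = fits$global$method,
      sign_mismatches = sum(fits$sign_agreement$sign_mismatch)
    )
  }

  recovery <- NULL
  if (!is.null(truth)) {
    # single-run comparison of the recovered global estimates with truth
    tag <- cutoff_tag(cfg$prevalence_cutoffs[1])
    models <- jsonlite::read_json(
      file.path(out_dir, paste0("models_", tag, ".json")),
      simplifyVector = TRUE)
    fe <- models$global$fixed_effects
    fe <- fe[fe$term %in% names(TERM_TO_GAMMA), ]
    truth_vec <- unlist(truth[TERM_TO_GAMMA[fe$term]])
    recovery <- tibble::tibble(
      term = fe$term, truth = unname(truth_vec), estimate = fe$estimate,
      error = fe$estimate - unname(truth_vec),
      ci_covers = fe$ci_low <= truth_vec & truth_vec <= fe$ci_high)
    jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("citsciBias")),
    seed = cfg$seed,
    mode = cfg$mode,
    config = cfg[c("mode", "seed", "prevalence_cutoffs", "zero_policy")],
    stages = list(
      checklists_in = filtered$report$n_input,
      checklists_retained = filtered$report$n_retained,
      checklists_removed = filtered$report$n_removed,
      filter_report = as.list(filtered$report$removed_by),
      ebird_obs_in = nrow(ebird_obs),
      ebird_obs_on_retained = nrow(obs_retained),
      inat_obs_in = nrow(inat_obs),
      prevalence_pairs = nrow(prevalence),
      per_cutoff = per_cutoff
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, recovery = recovery,
                 correlations = correlations))
}
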