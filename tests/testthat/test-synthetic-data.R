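test_that("trait generator configs reject invalid parameters by name", {
  expect_error(trait_gen_config(0), "n_species")
  expect_error(trait_gen_config(10, body_mass_log10_sd = -1),
               "body_mass_log10_sd")
  expect_error(trait_gen_config(10, iucn_probs = c(0.5, 0.4, 0.2)),
               "iucn_probs")
  expect_error(
    bundle_config(contamination = list(incomplete = -0.1,
                                       bad_protocol = 0, too_far = 0,
                                       too_short = 0, too_long = 0)),
    "nonnegative")
})

test_that("generated traits respect bounds and degenerate distributions", {
  cfg <- trait_gen_config(50, iucn_probs = c(1, 0, 0), seed = 7)
  tr <- generate_traits(cfg)
  expect_equal(nrow(tr$species), 50)
  expect_true(all(tr$species$body_mass_g > 0))
  expect_true(all(tr$species$flock_size >= 1))
  expect_true(all(tr$species$iucn_category == "LeastConcern"))
  expect_equal(nrow(tr$patches), 50 * 12)  # six patches per sex
  chan <- c(tr$patches$R, tr$patches$G, tr$patches$B)
  expect_true(all(chan >= 0 & chan <= 255))
})

test_that("generation is deterministic given the seed", {
  cfg <- trait_gen_config(30, seed = 123)
  a <- generate_traits(cfg)
  b <- generate_traits(cfg)
  expect_identical(a$species, b$species)
  expect_identical(a$patches, b$patches)

  bc <- bundle_config(states = c("AA", "BB"), checklists_per_state = 50,
                      seed = 5)
  x <- generate_event_level(bc)
  y <- generate_event_level(bc)
  expect_identical(x$checklists, y$checklists)
  expect_identical(x$ebird_obs, y$ebird_obs)
  expect_identical(x$inat_obs, y$inat_obs)
})

test_that("IUCN category frequencies match the configured probabilities", {
  probs <- c(LeastConcern = 0.92, NearThreatened = 0.04,
             Vulnerable = 0.03, Endangered = 0.01)
  tr <- generate_traits(trait_gen_config(2000, iucn_probs = probs,
                                         seed = 11))
  obs <- table(factor(tr$species$iucn_category, levels = names(probs)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("deterministic linear case reproduces the planted line exactly", {
  tr <- generate_traits(trait_gen_config(20, seed = 3))
  tt <- build_trait_table(tr$species, patches = tr$patches)
  truth <- planted_effects(c("X", "Y"), slope_b = 1,
                           state_intercept_mean = -2,
                           state_intercept_sd = 0, noise_sd = 0, seed = 3)
  counts <- generate_counts_direct(tt, c("X", "Y"),
                                   effort = c(X = 1e5, Y = 1e5), truth,
                                   seed = 3)
  expect_equal(counts$latent_log10_inat, log10(counts$n_ebird) - 2,
               tolerance = 1e-12)
  expect_true(all(counts$n_inat >= 0))
  expect_identical(counts$zero_inat, counts$n_inat == 0L)
})

test_that("unknown states and bad effort are rejected", {
  tr <- generate_traits(trait_gen_config(5, seed = 1))
  tt <- build_trait_table(tr$species, patches = tr$patches)
  truth <- planted_effects("X", seed = 1)
  expect_error(
    generate_counts_direct(tt, c("X", "Z"), c(X = 10, Z = 10), truth),
    "Z")
  expect_error(
    generate_counts_direct(tt, "X", c(X = -5), truth), "effort")
})

test_that("planted contamination is recorded and zero rates contaminate nothing", {
  clean <- bundle_config(
    states = c("AA", "BB"), checklists_per_state = 60,
    contamination = list(incomplete = 0, bad_protocol = 0, too_far = 0,
                         too_short = 0, too_long = 0),
    include_boundaries = FALSE, seed = 2)
  b <- generate_event_level(clean)
  expect_true(all(b$labels$pass))

  dirty <- bundle_config(states = c("AA", "BB"), checklists_per_state = 100,
                         seed = 2)
  d <- generate_event_level(dirty)
  rates <- unlist(dirty$contamination)
  expect_equal(sum(d$labels$fail_incomplete), round(rates["incomplete"] * 200),
               ignore_attr = TRUE)
  expect_equal(sum(!d$labels$pass), sum(round(rates * 200)))
  # violations are planted disjointly
  fail_mat <- as.matrix(d$labels[, startsWith(names(d$labels), "fail_")])
  expect_true(all(rowSums(fail_mat) <= 1))
})

test_that("boundary-effort checklists are generated as passing", {
  b <- generate_event_level(bundle_config(states = "AA",
                                          checklists_per_state = 80,
                                          seed = 4))
  cl <- b$checklists
  lab <- b$labels
  pass_ids <- lab$checklist_id[lab$pass]
  at5 <- intersect(
    cl$checklist_id[!is.na(cl$duration_min) & cl$duration_min == 5],
    pass_ids)
  at240 <- intersect(
    cl$checklist_id[!is.na(cl$duration_min) & cl$duration_min == 240],
    pass_ids)
  at5km <- intersect(
    cl$checklist_id[!is.na(cl$distance_km) & cl$distance_km == 5],
    pass_ids)
  # the planted boundary checklists exist, pass, and survive the filter
  expect_true(length(at5) >= 1 && length(at240) >= 1 && length(at5km) >= 1)
  res <- filter_checklists(b$checklists)
  expect_true(all(c(at5, at240, at5km) %in% res$checklists$checklist_id))
})

test_that("every observation references a checklist and a known species", {
  b <- generate_event_level(bundle_config(states = c("AA", "BB"),
                                          checklists_per_state = 50,
                                          seed = 9))
  expect_true(all(b$ebird_obs$checklist_id %in% b$checklists$checklist_id))
  expect_true(all(b$ebird_obs$species %in% b$traits$species$species))
  expect_true(all(b$inat_obs$species %in% b$traits$species$species))
  expect_true(any(b$ebird_obs$count == "X"))
})
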