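test_that("distance from brown evaluates the RGB formula exactly", {
  # distance to the reference itself is zero
  expect_equal(
    distance_from_brown(patch_row("a", 102, 68, 0))$distance_from_brown, 0)
  # one-axis displacement
  expect_equal(
    distance_from_brown(patch_row("a", 102, 68, 255))$distance_from_brown,
    255)
  # white patch: sqrt((255-102)^2 + (255-68)^2 + (255-0)^2)
  expect_equal(
    distance_from_brown(patch_row("a", 255, 255, 255))$distance_from_brown,
    sqrt(153^2 + 187^2 + 255^2))
  # the maximum over patches and sexes wins
  two <- dplyr::bind_rows(patch_row("a", 102, 68, 0, sex = "male"),
                          patch_row("a", 102, 68, 100, sex = "female",
                                    patch = "nape"))
  expect_equal(two |> distance_from_brown() |> dplyr::pull(), 100)
})

test_that("the printed-variant brown reference transposes G and B", {
  ref <- brown_reference(printed = TRUE)
  expect_equal(unname(ref[c("R", "G", "B")]), c(102, 0, 68))
  d <- distance_from_brown(patch_row("a", 102, 0, 68), reference = ref)
  expect_equal(d$distance_from_brown, 0)
})

test_that("relative luminance uses the 0.2126/0.7152/0.0722 weights", {
  expect_equal(
    relative_luminance(patch_row("a", 255, 255, 255))$relative_luminance,
    255)
  expect_equal(
    relative_luminance(patch_row("a", 0, 0, 0))$relative_luminance, 0)
  expect_equal(
    relative_luminance(patch_row("a", 255, 0, 0))$relative_luminance,
    54.213)
  expect_error(relative_luminance(patch_row("a", 300, 0, 0)), "255")
})

test_that("color index endpoints and midpoints match a hand computation", {
  # five species, one patch each; components computed by hand:
  #   species  patch            dist-from-brown          luminance
  #   s1       (102, 68, 0)     0                        70.3188
  #   s2       (255, 255, 255)  sqrt(123403) = 351.2876  255
  #   s3       (102, 68, 255)   255                      88.7298
  #   s4       (0, 0, 0)        sqrt(15028)  = 122.5888  0
  #   s5       (255, 0, 0)      sqrt(28033)  = 167.4306  54.213
  patches <- dplyr::bind_rows(
    patch_row("s1", 102, 68, 0), patch_row("s2", 255, 255, 255),
    patch_row("s3", 102, 68, 255), patch_row("s4", 0, 0, 0),
    patch_row("s5", 255, 0, 0))
  ci <- color_index(patches)
  ci <- ci[match(paste0("s", 1:5), ci$species), ]

  d <- c(0, sqrt(153^2 + 187^2 + 255^2), 255, sqrt(102^2 + 68^2),
         sqrt(153^2 + 68^2))
  l <- c(0.2126 * 102 + 0.7152 * 68, 255,
         0.2126 * 102 + 0.7152 * 68 + 0.0722 * 255, 0, 0.2126 * 255)
  ds <- (d - min(d)) / (max(d) - min(d))
  ls <- (l - min(l)) / (max(l) - min(l))
  comb <- 0.5 * ds + 0.5 * ls
  expected <- (comb - min(comb)) / (max(comb) - min(comb))
  expect_equal(ci$color_index, expected, tolerance = 1e-12)
  # endpoint species hit exactly 0 and 1
  expect_equal(min(ci$color_index), 0)
  expect_equal(max(ci$color_index), 1)
  # s2 attains the max of both components, s4 would be the min of
  # luminance but not distance; the rescale still pins the extremes
  expect_equal(ci$color_index[ci$species == "s2"], 1)
})

test_that("color index is invariant to patch labels and row order", {
  tr <- generate_traits(trait_gen_config(12, seed = 44))
  a <- color_index(tr$patches)
  shuffled <- tr$patches[sample(nrow(tr$patches)), ]
  shuffled$patch <- sample(shuffled$patch)  # relabel patches
  b <- color_index(shuffled)
  expect_equal(dplyr::arrange(a, species), dplyr::arrange(b, species),
               tolerance = 1e-12)
})

test_that("adding a species rescales the index but not the components", {
  tr <- generate_traits(trait_gen_config(8, seed = 45))
  base <- color_index(tr$patches)
  extra <- dplyr::bind_rows(tr$patches, patch_row("zz", 10, 200, 30))
  wider <- color_index(extra)
  joined <- dplyr::inner_join(base, wider, by = "species",
                              suffix = c("_a", "_b"))
  expect_equal(joined$distance_from_brown_a, joined$distance_from_brown_b)
  expect_equal(joined$relative_luminance_a, joined$relative_luminance_b)
})

test_that("constant color components raise an instructive error", {
  same <- dplyr::bind_rows(patch_row("a", 10, 10, 10),
                           patch_row("b", 10, 10, 10))
  expect_error(color_index(same), "constant")
  expect_error(color_index(patch_row("a", 1, 2, 3)), "at least 2 species")
})

test_that("flock size averages counted reports and excludes X records", {
  obs <- tibble::tibble(
    checklist_id = sprintf("c%d", 1:7),
    species = c("a", "a", "a", "b", "b", "x", "x"),
    count = c("1", "1", "4", "3", "X", "X", "X"))
  fs <- flock_size(obs)
  expect_equal(fs$flock_size[fs$species == "a"], 2)
  expect_equal(fs$flock_size[fs$species == "b"], 3)   # X dropped
  expect_true(is.na(fs$flock_size[fs$species == "x"]))  # only-X species
  expect_equal(fs$n_x[fs$species == "x"], 2)

  # brute-force mean on a random fixture
  fx <- random_obs_fixture(seed = 8)
  got <- flock_size(fx$ebird_obs)
  for (sp in sample(got$species, 5)) {
    vals <- as.numeric(fx$ebird_obs$count[fx$ebird_obs$species == sp])
    expect_equal(got$flock_size[got$species == sp], mean(vals))
  }
  expect_true(all(got$flock_size >= 1, na.rm = TRUE))
})

test_that("IUCN encoding is ordinal with LC highest and NT lowest", {
  expect_equal(encode_iucn(c("Least Concern", "Vulnerable",
                             "Near Threatened")), c(2, 1, 0))
  expect_equal(encode_iucn(c("LC", "VU", "NT")), c(2, 1, 0))
  expect_true(is.na(encode_iucn("Endangered")))
  expect_true(is.na(encode_iucn("Critically Endangered")))
  expect_error(encode_iucn("Common"), "accepted|Accepted")
  # order-preserving under the stated ordering LC > VU > NT
  sc <- encode_iucn(c("LeastConcern", "Vulnerable", "NearThreatened"))
  expect_true(all(diff(sc) < 0))
})

test_that("the trait table flags missing components instead of inventing them", {
  species_tbl <- tibble::tibble(
    species = c("a", "b"), body_mass_g = c(10, 100),
    iucn_category = c("LC", "Endangered"))
  tt <- build_trait_table(species_tbl)  # no patches, no observations
  expect_equal(tt$log10_body_mass, c(1, 2))
  expect_true(all(is.na(tt$color_index)))
  expect_true(all(is.na(tt$log10_flock_size)))
  expect_true(is.na(tt$iucn_score[tt$species == "b"]))
  expect_error(
    build_trait_table(dplyr::mutate(species_tbl, body_mass_g = c(-1, 5))),
    "positive")
})
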