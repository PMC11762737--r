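test_that("simulate_yule_tree is ultrametric, sized, and deterministic", {
  t2 <- simulate_yule_tree(2, 1, seed = 5)
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(t2$edge.length[1], t2$edge.length[2])

  t50 <- simulate_yule_tree(50, 1, seed = 6)
  expect_equal(ape::Ntip(t50), 50L)
  expect_true(ape::is.ultrametric(t50, tol = 1e-9))

  expect_identical(write_newick(simulate_yule_tree(20, 1, seed = 9)),
                   write_newick(simulate_yule_tree(20, 1, seed = 9)))
})

test_that("simulate_dataset is fully deterministic under a fixed seed", {
  d1 <- simulate_dataset(sim_config(n_species = 10, seed = 77))
  d2 <- simulate_dataset(sim_config(n_species = 10, seed = 77))
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  expect_identical(d1$individuals, d2$individuals)
  expect_identical(d1$latent, d2$latent)
})

test_that("degenerate regimes behave as stated", {
  tr <- simulate_yule_tree(10, 1, seed = 8)
  # no asymmetry sources -> asymmetry exactly 0
  cfg0 <- sim_config(n_species = 10, delta = 0, beta_size = 0, beta_risk = 0,
                     sd_species_noise = 0)
  lat0 <- simulate_species_traits(tr, cfg0)
  expect_true(all(lat0$asym == 0))
  expect_equal(lat0$log10_left, lat0$log10_right)

  # sigma2 = 0 -> all species share the regional mean
  cfgs <- sim_config(n_species = 10, sigma2 = 0)
  lats <- simulate_species_traits(tr, cfgs)
  expect_equal(as.vector(tapply(lats$z, lats$region, sd)), rep(0, 4))
})

test_that("noiseless individuals round-trip the latent volumes", {
  tr <- simulate_yule_tree(6, 1, seed = 10)
  cfg <- sim_config(n_species = 6, delta = 0.02, beta_size = 0,
                    beta_risk = 0, sd_species_noise = 0,
                    cv_measurement = 0, cv_individual = 0,
                    n_individuals_range = c(1L, 1L))
  lat <- simulate_species_traits(tr, cfg)
  ind <- simulate_individuals(lat, cfg)
  for (r in REGIONS) {
    v <- ellipsoid_volume(ind[[paste0(r, "_left_length_mm")]],
                          ind[[paste0(r, "_left_width_mm")]],
                          ind[[paste0(r, "_left_height_mm")]])
    v_lat <- 10^lat$log10_left[lat$region == r][match(ind$species,
                                                      lat$species[lat$region == r])]
    expect_equal(v, v_lat, tolerance = 1e-12)
  }
  # delta fixture: species mean-log difference is exactly delta
  s <- species_summaries(ind)
  expect_equal(s$mean_log10_left - s$mean_log10_right,
               rep(0.02, nrow(s)), tolerance = 1e-10)
  expect_true(all(s$direction == "left_larger"))
})

test_that("aspect-ratio inversion reproduces the requested volume", {
  asp <- c(2, 1, 1)
  V <- 7.3
  s <- (V * 6 * 1.43 / (pi * prod(asp)))^(1 / 3)
  L <- asp[1] * s; W <- asp[2] * s; H <- asp[3] * s
  expect_equal(L, 2 * W)
  expect_equal(H, W)
  expect_equal(ellipsoid_volume(L, W, H), V, tolerance = 1e-12)
})

test_that("mixed-sign asymmetry yields the constructed partition", {
  # hand-built latent table: 4 species left-larger, 4 right-larger
  tr <- simulate_yule_tree(8, 1, seed = 12)
  sp <- tr$tip.label
  a <- rep(c(0.03, -0.03), each = 4)
  lat <- do.call(rbind, lapply(REGIONS, function(r) {
    data.frame(species = sp, region = r, z = 4, asym = a,
               log10_left = 4 + a / 2, log10_right = 4 - a / 2,
               predation_risk = 5)
  }))
  cfg <- sim_config(n_species = 8, cv_measurement = 0, cv_individual = 0,
                    n_individuals_range = c(1L, 1L))
  ind <- simulate_individuals(lat, cfg)
  s <- species_summaries(ind)
  part <- classify_direction(s, "whole_brain")
  expect_setequal(part$left_larger, sp[1:4])
  expect_setequal(part$right_larger, sp[5:8])
})

test_that("simulated BM covariance converges to sigma2 * C_lambda", {
  tr <- simulate_yule_tree(5, 1, seed = 13)
  cfg <- sim_config(n_species = 5, sigma2 = 0.1, lambda_true = 0.7,
                    sd_species_noise = 0)
  target <- 0.1 * lambda_transform(vcv_matrix(tr), 0.7)
  frob <- function(nrep) {
    Z <- replicate(nrep, {
      lat <- simulate_species_traits(tr, cfg)
      lat$z[lat$region == "whole_brain"]
    })
    emp <- stats::cov(t(Z))
    sqrt(sum((emp - target)^2)) / sqrt(sum(target^2))
  }
  set.seed(14)
  e_small <- frob(300)
  e_big <- frob(4000)
  expect_lt(e_big, e_small)   # error shrinks with replicates
  expect_lt(e_big, 0.15)
})

test_that("fixture write/read round-trips the dataset exactly", {
  ds <- simulate_dataset(sim_config(n_species = 6, seed = 15))
  dir <- file.path(tempdir(), "fixture_rt")
  paths <- write_fixture(ds, dir)
  expect_true(all(file.exists(paths)))
  back <- read_fixture(dir)
  expect_equal(back$individuals, ds$individuals, tolerance = 0)
  expect_equal(back$covariates, ds$covariates, tolerance = 0)
  expect_identical(write_newick(back$tree), write_newick(ds$tree))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$config$seed, 15)
  # fixture flows through the pipeline with no edits
  rep <- run_pipeline(paths[["individuals"]], paths[["covariates"]],
                      paths[["tree"]], out_dir = NULL)
  expect_s3_class(rep, "asym_report")
})
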