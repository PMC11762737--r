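# Synthetic data: Yule trees, Brownian-motion evolution of log10 brain-region
# sizes with an injected directional-asymmetry signal, and individual-level
# linear measurements with lognormal noise.  Replaces the unreleased field
# data with a dataset whose statistical structure matches what the analysis
# assumes, with all latent truth recorded.

# Region-level defaults: log10 mm^3 hemisphere means roughly matching the
# magnitudes of published anuran species summaries, and fixed L:W:H aspect
# ratios used when inverting the ellipsoid volume into linear measurements.
REGION_MU <- c(olfactory_bulb = 2.7, telencephalon = 3.7,
               optic_tectum = 3.4, whole_brain = 4.3)
REGION_ASPECT <- list(olfactory_bulb = c(1.4, 0.8, 0.6),
                      telencephalon = c(1.6, 1.0, 0.8),
                      optic_tectum = c(1.2, 1.0, 0.9),
                      whole_brain = c(2.0, 1.2, 0.9))

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a world resembling the anuran study the pipeline is
#' designed for: ~99 species, species mean log10 hemisphere volumes around
#' 2.7-4.4 with SD 0.3-0.4 log units, 2-8 individuals per species, small
#' directional asymmetry of either sign, and a weak link between asymmetry
#' and a predation-risk covariate.
#'
#' @param n_species Number of species (tree tips).
#' @param birth_rate Yule (pure-birth) speciation rate.
#' @param sigma2 Brownian-motion rate of log10 volume per unit branch length.
#' @param lambda_true Pagel's lambda used to rescale the simulation
#'   covariance.
#' @param delta Directional-asymmetry offset on the log10 scale (mean of
#'   species log10 left minus log10 right); 0 gives purely fluctuating
#'   species-level asymmetry of either sign.
#' @param beta_size Slope of log-scale asymmetry on standardized total brain
#'   size.
#' @param beta_risk Slope of log-scale asymmetry on standardized log10
#'   predation risk.
#' @param sd_species_noise SD of species-level non-phylogenetic asymmetry
#'   noise (log10 units).
#' @param phylo_asym_noise When `TRUE`, the asymmetry noise is drawn with
#'   the same lambda-rescaled phylogenetic covariance (marginal SD kept at
#'   `sd_species_noise`); default `FALSE` (iid).
#' @param n_individuals_range Integer pair: min/max individuals per species.
#' @param cv_measurement Coefficient of variation of the lognormal
#'   measurement noise applied to each recorded side volume.
#' @param cv_individual Coefficient of variation of the lognormal
#'   between-individual (biological) size factor within species.
#' @param n_replicates Replicate measurements per individual (1 = none).
#' @param risk_meanlog,risk_sdlog Lognormal parameters of predation risk
#'   (snakes per km^2), simulated independently of the tree.
#' @param seed RNG seed consumed by [simulate_dataset()].
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 99, birth_rate = 1, sigma2 = 0.1,
                       lambda_true = 1, delta = 0, beta_size = 0.02,
                       beta_risk = 0.008, sd_species_noise = 0.01,
                       phylo_asym_noise = FALSE,
                       n_individuals_range = c(2L, 8L),
                       cv_measurement = 0.02, cv_individual = 0.1,
                       n_replicates = 1L,
                       risk_meanlog = 1, risk_sdlog = 1, seed = 1L) {
  cfg <- list(n_species = as.integer(n_species), birth_rate = birth_rate,
              sigma2 = sigma2, lambda_true = lambda_true, delta = delta,
              beta_size = beta_size, beta_risk = beta_risk,
              sd_species_noise = sd_species_noise,
              phylo_asym_noise = isTRUE(phylo_asym_noise),
              n_individuals_range = as.integer(n_individuals_range),
              cv_measurement = cv_measurement,
              cv_individual = cv_individual,
              n_replicates = as.integer(n_replicates),
              risk_meanlog = risk_meanlog, risk_sdlog = risk_sdlog,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 2L, birth_rate > 0, sigma2 >= 0,
              lambda_true >= 0, lambda_true <= 1, sd_species_noise >= 0,
              length(n_individuals_range) == 2L,
              n_individuals_range[1] >= 1L,
              n_individuals_range[2] >= n_individuals_range[1],
              cv_measurement >= 0, cv_individual >= 0, n_replicates >= 1L)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric pure-birth (Yule) phylogeny
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Optional seed; when given the simulation is reproducible on
#'   its own, otherwise the current RNG stream is consumed.
#' @return A `"phylo"` object with tips `sp001, sp002, ...`.
#' @export
simulate_yule_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  stopifnot(n_species >= 2L, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tr
}

# sdlog of a lognormal with mean 1 and coefficient of variation cv.
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Multiplicative lognormal noise with mean 1 and the given CV.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- lnorm_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# MVN draw with mean vector mu and covariance V (V may be rank deficient
# only when it is exactly 0).
rmvn_one <- function(mu, V) {
  if (all(V == 0)) return(mu)
  mu + drop(crossprod(chol(V), stats::rnorm(length(mu))))
}

#' Simulate species-level latent traits on a tree
#'
#' Draws, for each brain region, species log10 base sizes
#' `z ~ MVN(mu_region, sigma2 * C_lambda)` under Brownian motion with the
#' lambda-rescaled covariance; a per-species asymmetry
#' `a = delta + beta_size * std(size) + beta_risk * std(log10 risk) + noise`
#' splits the base size symmetrically into
#' `log10 left = z + a/2`, `log10 right = z - a/2`, so that total size is
#' unaffected by asymmetry.  Predation risk is lognormal and
#' tree-independent.  Consumes the current RNG stream in the order: risk,
#' then per region (base size, then asymmetry noise).
#'
#' @param tree A `"phylo"` object.
#' @param config A [sim_config()].
#' @return Data frame with one row per species x region: `species, region,
#'   z, asym, log10_left, log10_right, predation_risk`, with the config and
#'   standardized drivers attached as attributes `config`, `std_size`,
#'   `std_risk`.
#' @export
simulate_species_traits <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_phylogeny(tree)
  sp <- tree$tip.label
  n <- length(sp)
  C <- vcv_matrix(tree)
  Cl <- lambda_transform(C, config$lambda_true)

  risk <- stats::rlnorm(n, config$risk_meanlog, config$risk_sdlog)
  std_risk <- standardize(log10(risk))

  # base sizes per region (whole brain drawn last drives the size slope;
  # draw it first so std(size) is available to every region)
  draw_z <- function(mu) rmvn_one(rep(mu, n), config$sigma2 * Cl)
  z <- list()
  z$whole_brain <- draw_z(REGION_MU[["whole_brain"]])
  std_size <- if (stats::sd(z$whole_brain) > 1e-12) {
    standardize(z$whole_brain)
  } else rep(0, n)
  for (r in setdiff(REGIONS, "whole_brain")) z[[r]] <- draw_z(REGION_MU[[r]])

  noise_cov <- if (config$phylo_asym_noise && config$sd_species_noise > 0) {
    config$sd_species_noise^2 * Cl / mean(diag(Cl))
  } else NULL
  out <- do.call(rbind, lapply(REGIONS, function(r) {
    eps <- if (!is.null(noise_cov)) {
      rmvn_one(rep(0, n), noise_cov)
    } else stats::rnorm(n, 0, config$sd_species_noise)
    a <- config$delta + config$beta_size * std_size +
      config$beta_risk * std_risk + eps
    data.frame(species = sp, region = r, z = z[[r]], asym = a,
               log10_left = z[[r]] + a / 2, log10_right = z[[r]] - a / 2,
               predation_risk = risk, row.names = NULL)
  }))
  attr(out, "config") <- config
  attr(out, "std_size") <- std_size
  attr(out, "std_risk") <- std_risk
  out
}

#' Simulate individual-level linear measurements from latent species traits
#'
#' For each species, draws `n_i` individuals uniformly within
#' `n_individuals_range`.  Each individual carries a lognormal biological
#' size factor (CV `cv_individual`) applied to all its structures; each
#' recorded side volume is further multiplied by lognormal measurement noise
#' (CV `cv_measurement`), independently per replicate.  Volumes are inverted
#' into length/width/height under fixed per-region aspect ratios so that
#' [ellipsoid_volume()] recovers them exactly.  SVL is allometric in whole
#' brain size: `log10 SVL = 0.8 + 0.25 * (z_whole - mean) + N(0, 0.03)`.
#'
#' @param latent Output of [simulate_species_traits()].
#' @param config A [sim_config()].
#' @return Data frame in the individuals schema (one row per individual, or
#'   per replicate when `n_replicates > 1`, with a `replicate` column).
#' @export
simulate_individuals <- function(latent, config) {
  stopifnot(inherits(config, "sim_config"))
  sp_list <- unique(latent$species)
  mu_whole <- mean(latent$z[latent$region == "whole_brain"])
  rows <- list()
  for (s in sp_list) {
    lat <- latent[latent$species == s, , drop = FALSE]
    rng <- config$n_individuals_range
    n_i <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    z_w <- lat$z[lat$region == "whole_brain"]
    for (i in seq_len(n_i)) {
      sex <- sample(c("male", "female"), 1L)
      svl <- 10^(0.8 + 0.25 * (z_w - mu_whole) + stats::rnorm(1, 0, 0.03))
      g <- rlnorm_cv(1L, config$cv_individual)
      for (k in seq_len(config$n_replicates)) {
        row <- list(species = s,
                    individual_id = sprintf("%s_i%02d", s, i),
                    sex = sex, svl_mm = svl)
        if (config$n_replicates > 1L) row$replicate <- k
        for (r in REGIONS) {
          asp <- REGION_ASPECT[[r]]
          for (side in c("left", "right")) {
            v_lat <- 10^lat[[paste0("log10_", side)]][lat$region == r]
            v <- v_lat * g * rlnorm_cv(1L, config$cv_measurement)
            scale <- (v * 6 * 1.43 / (pi * prod(asp)))^(1 / 3)
            dims <- asp * scale
            row[[meas_col(r, side, "length")]] <- dims[1]
            row[[meas_col(r, side, "width")]] <- dims[2]
            row[[meas_col(r, side, "height")]] <- dims[3]
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Simulate a complete dataset
#'
#' Seeds the RNG from `config$seed` and consumes one stream in documented
#' order: tree, then species traits (risk, base sizes, asymmetry noise),
#' then individuals.
#'
#' @param config A [sim_config()].
#' @return List of class `"asym_dataset"`: `tree`, `individuals`,
#'   `covariates` (species, predation_risk, n_individuals), `latent`,
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_species, config$birth_rate)
  latent <- simulate_species_traits(tree, config)
  individuals <- simulate_individuals(latent, config)
  n_by_sp <- tapply(individuals$individual_id, individuals$species,
                    function(x) length(unique(x)))
  risk_by_sp <- latent$predation_risk[latent$region == REGIONS[1]]
  names(risk_by_sp) <- latent$species[latent$region == REGIONS[1]]
  covariates <- data.frame(species = tree$tip.label,
                           predation_risk = as.vector(risk_by_sp[tree$tip.label]),
                           n_individuals = as.integer(n_by_sp[tree$tip.label]),
                           row.names = NULL)
  structure(list(tree = tree, individuals = individuals,
                 covariates = covariates, latent = latent, config = config),
            class = "asym_dataset")
}

# Format numerics with enough digits to round-trip doubles through text.
fmt_full <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Emits `individuals.csv`, `covariates.csv`, `tree.nwk` and `truth.json`
#' (config plus latent table) into `directory`.  Numeric columns are written
#' with 17 significant digits so [read_fixture()] reproduces the dataset
#' exactly.
#'
#' @param dataset An `"asym_dataset"`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "asym_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(individuals = file.path(directory, "individuals.csv"),
             covariates = file.path(directory, "covariates.csv"),
             tree = file.path(directory, "tree.nwk"),
             truth = file.path(directory, "truth.json"))
  utils::write.csv(fmt_full(dataset$individuals), paths["individuals"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt_full(dataset$covariates), paths["covariates"],
                   row.names = FALSE, quote = FALSE)
  write_newick(dataset$tree, paths["tree"])
  truth <- list(config = unclass(dataset$config), latent = dataset$latent)
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read a fixture directory back into a dataset
#'
#' @param directory Directory written by [write_fixture()].
#' @return An `"asym_dataset"`.
#' @export
read_fixture <- function(directory) {
  ind <- utils::read.csv(file.path(directory, "individuals.csv"),
                         stringsAsFactors = FALSE)
  cov <- utils::read.csv(file.path(directory, "covariates.csv"),
                         stringsAsFactors = FALSE)
  tree <- read_newick(file.path(directory, "tree.nwk"))
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  cfg <- truth$config
  cfg$n_individuals_range <- as.integer(cfg$n_individuals_range)
  config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  structure(list(tree = tree, individuals = ind, covariates = cov,
                 latent = truth$latent, config = config),
            class = "asym_dataset")
}
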