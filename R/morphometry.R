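# Volumes, asymmetry indices, species summaries, direction labels,
# and measurement repeatability.

#' Brain regions handled by the pipeline
#' @export
REGIONS <- c("olfactory_bulb", "telencephalon", "optic_tectum", "whole_brain")

#' Ellipsoid volume from linear measurements
#'
#' `V = L * W * H * pi / (6 * 1.43)`, the standard ellipsoid approximation
#' for brain structures measured as greatest length, width and height, with
#' the 1.43 empirical correction for non-ellipsoid shape.  Vectorized.
#'
#' @param length_mm,width_mm,height_mm Positive lengths in mm.
#' @return Volume in mm^3.
#' @examples
#' ellipsoid_volume(1, 1, 1)   # pi / 8.58
#' @export
ellipsoid_volume <- function(length_mm, width_mm, height_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(!is.finite(height_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0) || any(height_mm <= 0)) {
    stop("all linear measurements must be positive and finite", call. = FALSE)
  }
  length_mm * width_mm * height_mm * pi / (6 * 1.43)
}

#' Signed relative asymmetry index
#'
#' `(left - right) / (0.5 * (left + right))`: the left-right difference
#' relative to the side mean.  Zero for perfect symmetry, positive when the
#' left side is larger, antisymmetric under side swap, invariant to common
#' rescaling, and bounded in (-2, 2).
#'
#' @param left_volume,right_volume Positive volumes.
#' @return Dimensionless signed index.
#' @export
asymmetry_index <- function(left_volume, right_volume) {
  if (any(!is.finite(left_volume)) || any(!is.finite(right_volume)) ||
      any(left_volume <= 0) || any(right_volume <= 0)) {
    stop("volumes must be positive and finite", call. = FALSE)
  }
  (left_volume - right_volume) / (0.5 * (left_volume + right_volume))
}

# Column name for one measurement in the individuals schema.
meas_col <- function(region, side, dim) {
  paste(region, side, paste0(dim, "_mm"), sep = "_")
}

# All measurement columns expected for a set of regions.
measurement_columns <- function(regions = REGIONS) {
  unlist(lapply(regions, function(r) {
    unlist(lapply(c("left", "right"), function(s) {
      paste(r, s, c("length_mm", "width_mm", "height_mm"), sep = "_")
    }))
  }), use.names = FALSE)
}

# Per-row volume for one region/side from an individuals data frame.
row_volume <- function(df, region, side) {
  ellipsoid_volume(df[[meas_col(region, side, "length")]],
                   df[[meas_col(region, side, "width")]],
                   df[[meas_col(region, side, "height")]])
}

#' Species-level summaries of volumes and asymmetry
#'
#' Collapses individual measurements to one row per species per region.
#' Volumes are computed per individual per side, log10-transformed, and
#' averaged across individuals (geometric means on the raw scale); if a
#' `replicate` column is present, replicates are averaged within individual
#' first.  The asymmetry index is computed from the back-transformed side
#' means.  Total brain size is the raw-scale sum of left and right
#' whole-brain volumes per individual, then log10, then averaged.
#'
#' @param records Data frame in the individuals schema: `species`,
#'   `individual_id`, `sex`, `svl_mm`, and
#'   `{region}_{side}_{length|width|height}_mm` columns; optional
#'   `replicate`.
#' @param risk_table Optional data frame with `species` and `predation_risk`
#'   (snakes per km^2).  Species missing from it get `NA` risk with a warning.
#' @param regions Regions to summarize (subset of [REGIONS]).
#' @param convention `"species_means"` (default): one index per species from
#'   side means.  `"individual_mean"`: mean of per-individual indices.
#' @param tie_tol Absolute tolerance on the mean-log left-right difference
#'   below which a species is called `tied`.
#' @return Long data frame: one row per species x region with columns
#'   `species, region, n, mean_log10_left, mean_log10_right, asym_index,
#'   direction, log10_total_brain, svl_log10, predation_risk`.
#' @export
species_summaries <- function(records, risk_table = NULL, regions = REGIONS,
                              convention = c("species_means", "individual_mean"),
                              tie_tol = 1e-12) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(records), nrow(records) > 0)
  regions <- match.arg(regions, REGIONS, several.ok = TRUE)
  need <- c("species", "individual_id", "svl_mm", measurement_columns(regions))
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("individuals table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$species <- normalize_taxon(records$species)

  # average replicates within individual on the log scale first
  has_rep <- "replicate" %in% names(records)
  per_region_logs <- function(df, region) {
    l <- log10(row_volume(df, region, "left"))
    r <- log10(row_volume(df, region, "right"))
    if (has_rep) {
      key <- interaction(df$species, df$individual_id, drop = TRUE)
      l <- tapply(l, key, mean)
      r <- tapply(r, key, mean)
      sp <- tapply(df$species, key, `[`, 1L)
      data.frame(species = as.vector(sp), log_l = as.vector(l),
                 log_r = as.vector(r))
    } else {
      data.frame(species = df$species, log_l = l, log_r = r)
    }
  }

  # total brain: raw-scale sum before log (needs whole_brain columns)
  tot <- NULL
  if (all(measurement_columns("whole_brain") %in% names(records))) {
    tv <- row_volume(records, "whole_brain", "left") +
      row_volume(records, "whole_brain", "right")
    ltv <- log10(tv)
    if (has_rep) {
      key <- interaction(records$species, records$individual_id, drop = TRUE)
      ltv <- as.vector(tapply(ltv, key, mean))
      spv <- as.vector(tapply(records$species, key, `[`, 1L))
    } else {
      spv <- records$species
    }
    tot <- vapply(split(ltv, spv), mean, 0)
  }

  lsvl <- log10(records$svl_mm)
  if (has_rep) {
    key <- interaction(records$species, records$individual_id, drop = TRUE)
    lsvl <- as.vector(tapply(lsvl, key, mean))
    spv2 <- as.vector(tapply(records$species, key, `[`, 1L))
  } else {
    spv2 <- records$species
  }
  svl_by_sp <- vapply(split(lsvl, spv2), mean, 0)
  n_by_sp <- vapply(split(lsvl, spv2), length, 0L)

  out <- do.call(rbind, lapply(regions, function(region) {
    d <- per_region_logs(records, region)
    ml <- vapply(split(d$log_l, d$species), mean, 0)
    mr <- vapply(split(d$log_r, d$species), mean, 0)
    sp <- names(ml)
    if (convention == "species_means") {
      ai <- asymmetry_index(10^ml, 10^mr)
    } else {
      ii <- asymmetry_index(10^d$log_l, 10^d$log_r)
      ai <- as.vector(vapply(split(ii, d$species), mean, 0))
    }
    diff <- ml - mr
    dir <- ifelse(abs(diff) < tie_tol, "tied",
                  ifelse(diff > 0, "left_larger", "right_larger"))
    data.frame(species = sp, region = region, n = as.integer(n_by_sp[sp]),
               mean_log10_left = as.vector(ml), mean_log10_right = as.vector(mr),
               asym_index = as.vector(ai), direction = dir,
               log10_total_brain = if (is.null(tot)) NA_real_ else
                 as.vector(tot[sp]),
               svl_log10 = as.vector(svl_by_sp[sp]),
               row.names = NULL)
  }))

  out$predation_risk <- NA_real_
  if (!is.null(risk_table)) {
    stopifnot(all(c("species", "predation_risk") %in% names(risk_table)))
    risk_table$species <- normalize_taxon(risk_table$species)
    idx <- match(out$species, risk_table$species)
    out$predation_risk <- risk_table$predation_risk[idx]
    orphans <- unique(out$species[is.na(idx)])
    if (length(orphans)) {
      warning("species missing from risk table (risk set to NA): ",
              paste(orphans, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Partition species by direction of asymmetry
#'
#' @param summaries Output of [species_summaries()].
#' @param region One region name.
#' @return List with character vectors `left_larger`, `right_larger`, `tied`.
#' @export
classify_direction <- function(summaries, region) {
  s <- summaries[summaries$region == region, , drop = FALSE]
  if (nrow(s) == 0) stop("no summaries for region ", region, call. = FALSE)
  list(left_larger = s$species[s$direction == "left_larger"],
       right_larger = s$species[s$direction == "right_larger"],
       tied = s$species[s$direction == "tied"])
}

#' One-way intraclass correlation (repeatability)
#'
#' One-way ANOVA ICC for repeated measurements:
#' `R = (MS_between - MS_within) / (MS_between + (k0 - 1) * MS_within)`,
#' where `k0 = (N - sum(n_i^2)/N) / (s - 1)` is the unequal-group-size
#' effective replicate number.
#'
#' @param values Numeric measurements.
#' @param subject Factor-like subject (specimen) identifier, same length.
#' @return List of class `"repeatability"`: `R`, `n_subjects`,
#'   `n_replicates` (mean per subject), `ms_between`, `ms_within`.
#' @export
repeatability <- function(values, subject) {
  stopifnot(length(values) == length(subject))
  subject <- factor(subject)
  ni <- as.vector(table(subject))
  if (nlevels(subject) < 2L || any(ni < 1L) || all(ni < 2L)) {
    stop("need >= 2 subjects and replicated measurements", call. = FALSE)
  }
  N <- length(values)
  s <- nlevels(subject)
  gm <- mean(values)
  mi <- tapply(values, subject, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((values - mi[subject])^2)
  msb <- ssb / (s - 1)
  msw <- ssw / (N - s)
  if (msb <= 0 && msw <= 0) {
    stop("repeatability undefined: no variance between or within subjects",
         call. = FALSE)
  }
  k0 <- (N - sum(ni^2) / N) / (s - 1)
  R <- (msb - msw) / (msb + (k0 - 1) * msw)
  structure(list(R = R, n_subjects = s, n_replicates = mean(ni),
                 ms_between = msb, ms_within = msw),
            class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Intraclass correlation R = %.4f (%d subjects, mean %.2f replicates)\n",
              x$R, x$n_subjects, x$n_replicates))
  invisible(x)
}
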