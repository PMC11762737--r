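# End-to-end analysis: species summaries -> per-region direction partition
# -> phylogenetic paired t-tests within each direction group -> PGLS of the
# asymmetry index on total brain size and on predation risk -> pooled
# all-species paired tests -> individual-level ANCOVA.  All tables are
# written as CSV plus a JSON report with a provenance block; failures of
# individual models degrade to skip-with-reason rows, never silent omission.

ttest_row <- function(region, group, res, summaries_sub) {
  data.frame(region = region, group = group, n = res$n,
             mean_log10_left = mean(summaries_sub$mean_log10_left),
             sd_log10_left = stats::sd(summaries_sub$mean_log10_left),
             mean_log10_right = mean(summaries_sub$mean_log10_right),
             sd_log10_right = stats::sd(summaries_sub$mean_log10_right),
             mean_diff = res$mean_diff, lambda = res$lambda,
             t = res$t, df = res$df, p = res$p,
             degenerate = res$degenerate, skipped = FALSE,
             skip_reason = "", stringsAsFactors = FALSE)
}

skip_row_ttest <- function(region, group, reason) {
  data.frame(region = region, group = group, n = NA_integer_,
             mean_log10_left = NA_real_, sd_log10_left = NA_real_,
             mean_log10_right = NA_real_, sd_log10_right = NA_real_,
             mean_diff = NA_real_, lambda = NA_real_, t = NA_real_,
             df = NA_integer_, p = NA_real_, degenerate = NA,
             skipped = TRUE, skip_reason = reason, stringsAsFactors = FALSE)
}

pgls_rows <- function(region, group, predictor, fit) {
  terms <- names(fit$coefficients)
  data.frame(region = region, group = group, predictor_model = predictor,
             term = terms, n = fit$n, lambda = fit$lambda,
             lrt_p_lambda0 = fit$lrt_p_lambda0,
             lrt_p_lambda1 = fit$lrt_p_lambda1,
             r2 = fit$r2, r2_adj = fit$r2_adj,
             beta = as.vector(fit$coefficients), se = as.vector(fit$se),
             t = as.vector(fit$t), p = as.vector(fit$p),
             skipped = FALSE, skip_reason = "", stringsAsFactors = FALSE)
}

skip_row_pgls <- function(region, group, predictor, reason) {
  data.frame(region = region, group = group, predictor_model = predictor,
             term = NA_character_, n = NA_integer_, lambda = NA_real_,
             lrt_p_lambda0 = NA_real_, lrt_p_lambda1 = NA_real_,
             r2 = NA_real_, r2_adj = NA_real_, beta = NA_real_,
             se = NA_real_, t = NA_real_, p = NA_real_,
             skipped = TRUE, skip_reason = reason, stringsAsFactors = FALSE)
}

# Fit one PGLS table row set; any failure becomes a skip row with reason.
try_pgls <- function(region, group, predictor, s, x_col, tree, weighted,
                     fix_lambda, log_fn) {
  reason <- NULL
  s <- s[!is.na(s[[x_col]]), , drop = FALSE]
  if (nrow(s) < 5L) {
    reason <- sprintf("only %d species with complete data (need >= 5)", nrow(s))
  } else if (stats::sd(s$asym_index) < 1e-300) {
    reason <- "asymmetry index constant in group"
  }
  if (is.null(reason)) {
    res <- tryCatch({
      y <- standardize(s$asym_index)
      names(y) <- s$species
      xv <- if (x_col == "predation_risk") log10(s[[x_col]]) else s[[x_col]]
      X <- cbind(`(Intercept)` = 1, x = standardize(xv),
                 svl = standardize(s$svl_log10))
      colnames(X)[2] <- predictor
      w <- if (weighted) s$n else NULL
      fit_pgls(y, X, tree, weights = w, lambda = fix_lambda)
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "pgls_fit")) {
      if (res$flat_likelihood) {
        log_fn(sprintf("note: flat lambda likelihood for %s/%s/%s",
                       region, group, predictor))
      }
      return(pgls_rows(region, group, predictor, res))
    }
    reason <- res
  }
  log_fn(sprintf("skipped PGLS %s/%s/%s: %s", region, group, predictor, reason))
  skip_row_pgls(region, group, predictor, reason)
}

#' Pooled phylogenetic paired t-tests across all species
#'
#' Runs [phylo_paired_ttest()] per region over every species, with no
#' direction split.
#'
#' @param summaries Output of [species_summaries()].
#' @param tree A `"phylo"` object.
#' @param regions Regions to test.
#' @param fix_lambda Optional fixed lambda passed through.
#' @return Data frame with one row per region.
#' @export
pooled_paired_tests <- function(summaries, tree, regions = REGIONS,
                                fix_lambda = NULL) {
  do.call(rbind, lapply(regions, function(region) {
    s <- summaries[summaries$region == region, , drop = FALSE]
    if (nrow(s) < 3L) return(skip_row_ttest(region, "all", "fewer than 3 species"))
    res <- tryCatch({
      l <- s$mean_log10_left; r <- s$mean_log10_right
      names(l) <- names(r) <- s$species
      phylo_paired_ttest(l, r, tree, lambda = fix_lambda)
    }, error = function(e) conditionMessage(e))
    if (inherits(res, "phylo_ttest")) ttest_row(region, "all", res, s)
    else skip_row_ttest(region, "all", res)
  }))
}

#' Run the full asymmetry analysis pipeline
#'
#' @param individuals Path to the individuals CSV, or a data frame.
#' @param covariates Path to the per-species covariate CSV (`species`,
#'   `predation_risk`, `n_individuals`), or a data frame.
#' @param tree Path to a Newick file, or a `"phylo"` object.
#' @param out_dir Output directory for tables, report and log; `NULL` to
#'   skip writing.
#' @param regions Regions to analyze.
#' @param direction_split Run per-direction-group analyses (default `TRUE`).
#' @param fix_lambda Fix Pagel's lambda instead of ML estimation.
#' @param weighted Weight PGLS models by the number of individuals measured.
#' @param convention Asymmetry-index convention, see [species_summaries()].
#' @param tie_tol Tie tolerance for direction classification.
#' @return List of class `"asym_report"` with elements `summaries`,
#'   `partitions`, `paired_tests` (direction groups), `pooled_tests`,
#'   `pgls_size`, `pgls_risk`, `ancova`, `provenance`.
#' @export
run_pipeline <- function(individuals, covariates, tree, out_dir = NULL,
                         regions = REGIONS, direction_split = TRUE,
                         fix_lambda = NULL, weighted = TRUE,
                         convention = "species_means", tie_tol = 1e-12) {
  prov_files <- character(0)
  if (is.character(individuals)) {
    prov_files["individuals"] <- individuals
    individuals <- utils::read.csv(individuals, stringsAsFactors = FALSE)
  }
  if (is.character(covariates)) {
    prov_files["covariates"] <- covariates
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  }
  if (is.character(tree)) {
    prov_files["tree"] <- tree
    tree <- read_newick(tree)
  }
  validate_phylogeny(tree)
  regions <- match.arg(regions, REGIONS, several.ok = TRUE)

  log_lines <- character(0)
  log_fn <- function(msg) log_lines <<- c(log_lines, msg)

  individuals$species <- normalize_taxon(individuals$species)
  covariates$species <- normalize_taxon(covariates$species)
  orphans <- setdiff(unique(individuals$species), tree$tip.label)
  if (length(orphans)) {
    stop("species in data but absent from tree: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (!is_ultrametric_tree(tree)) {
    log_fn("warning: input tree is not ultrametric; proceeding")
  }

  summaries <- withCallingHandlers(
    species_summaries(individuals, covariates, regions,
                      convention = convention, tie_tol = tie_tol),
    warning = function(w) {
      log_fn(paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })

  partitions <- lapply(stats::setNames(regions, regions), function(r) {
    classify_direction(summaries, r)
  })

  paired <- NULL
  pgls_size <- NULL
  pgls_risk <- NULL
  if (direction_split) {
    for (region in regions) {
      part <- partitions[[region]]
      for (group in c("left_larger", "right_larger")) {
        sp <- part[[group]]
        s <- summaries[summaries$region == region &
                         summaries$species %in% sp, , drop = FALSE]
        if (length(sp) < 3L) {
          reason <- sprintf("only %d species in group", length(sp))
          log_fn(sprintf("skipped paired test %s/%s: %s", region, group, reason))
          paired <- rbind(paired, skip_row_ttest(region, group, reason))
        } else {
          res <- tryCatch({
            l <- s$mean_log10_left; r <- s$mean_log10_right
            names(l) <- names(r) <- s$species
            phylo_paired_ttest(l, r, tree, lambda = fix_lambda)
          }, error = function(e) conditionMessage(e))
          if (inherits(res, "phylo_ttest")) {
            paired <- rbind(paired, ttest_row(region, group, res, s))
          } else {
            log_fn(sprintf("skipped paired test %s/%s: %s", region, group, res))
            paired <- rbind(paired, skip_row_ttest(region, group, res))
          }
        }
        pgls_size <- rbind(pgls_size, try_pgls(
          region, group, "total_brain", s, "log10_total_brain", tree,
          weighted, fix_lambda, log_fn))
        pgls_risk <- rbind(pgls_risk, try_pgls(
          region, group, "predation_risk", s, "predation_risk", tree,
          weighted, fix_lambda, log_fn))
      }
    }
  }

  pooled <- pooled_paired_tests(summaries, tree, regions, fix_lambda)

  ancova <- tryCatch({
    wb <- measurement_columns("whole_brain")
    if (!all(wb %in% names(individuals))) stop("whole_brain columns absent")
    tot <- row_volume(individuals, "whole_brain", "left") +
      row_volume(individuals, "whole_brain", "right")
    ancova_species_effect(log10(tot), individuals$species,
                          log10(individuals$svl_mm))
  }, error = function(e) {
    log_fn(paste("skipped ANCOVA:", conditionMessage(e)))
    NULL
  })

  provenance <- list(
    package_version = as.character(utils::packageVersion("phylasym")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input_hashes = if (length(prov_files)) {
      as.list(tools::md5sum(prov_files))
    } else list(),
    config = list(regions = regions, direction_split = direction_split,
                  fix_lambda = fix_lambda, weighted = weighted,
                  convention = convention, tie_tol = tie_tol))

  report <- structure(list(summaries = summaries, partitions = partitions,
                           paired_tests = paired, pooled_tests = pooled,
                           pgls_size = pgls_size, pgls_risk = pgls_risk,
                           ancova = ancova, provenance = provenance,
                           log = log_lines),
                      class = "asym_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report to disk
#'
#' Emits `summaries.csv`, `paired_tests.csv`, `pooled_tests.csv`,
#' `pgls_size.csv`, `pgls_risk.csv`, `ancova.csv`, `report.json` and
#' `analysis.log` into `out_dir`.  Deterministic: identical inputs give
#' byte-identical tables.
#'
#' @param report An `"asym_report"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "asym_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(fmt_full(df), file.path(out_dir, name),
                       row.names = FALSE, quote = FALSE)
    }
  }
  wr(report$summaries, "summaries.csv")
  wr(report$paired_tests, "paired_tests.csv")
  wr(report$pooled_tests, "pooled_tests.csv")
  wr(report$pgls_size, "pgls_size.csv")
  wr(report$pgls_risk, "pgls_risk.csv")
  if (!is.null(report$ancova)) {
    wr(as.data.frame(unclass(report$ancova)), "ancova.csv")
  }
  json <- report[c("partitions", "provenance")]
  json$ancova <- if (is.null(report$ancova)) NULL else unclass(report$ancova)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(report$log, file.path(out_dir, "analysis.log"))
  invisible(out_dir)
}

#' @export
print.asym_report <- function(x, ...) {
  cat("Asymmetry analysis report\n")
  cat(sprintf("  %d species, regions: %s\n",
              length(unique(x$summaries$species)),
              paste(unique(x$summaries$region), collapse = ", ")))
  for (r in names(x$partitions)) {
    p <- x$partitions[[r]]
    cat(sprintf("  %s: %d left-larger, %d right-larger, %d tied\n", r,
                length(p$left_larger), length(p$right_larger),
                length(p$tied)))
  }
  if (!is.null(x$ancova)) print(x$ancova)
  if (length(x$log)) cat(sprintf("  %d log messages\n", length(x$log)))
  invisible(x)
}
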