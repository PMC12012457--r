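#' Pipeline configuration
#'
#' Collects and validates everything a full run needs: either an input
#' affiliation CSV plus registry CSV, or simulation settings for a
#' synthetic cohort; the censoring window; the NMR reporting periods; the
#' trend eligibility rule; the grouping; seeds; and the output directory.
#'
#' @param out_dir Output directory for all CSV products and the manifest.
#' @param affiliations,registry Optional paths to input CSVs (schemas:
#'   \code{author_id,year,region_id,country_id} and
#'   \code{region_id,country_id,continent_id[,group_label]}). When absent,
#'   a synthetic cohort is simulated.
#' @param simulate List of arguments for \code{\link{cohort_config}} (used
#'   only when no input files are given).
#' @param world List of arguments for \code{\link{build_world}} (ditto).
#' @param window Inclusive analysis window, default \code{1998:2017}.
#' @param nmr_periods List of year ranges for period NMRs; default the
#'   three six-year reporting periods 2000--2005, 2006--2011, 2012--2017.
#' @param rule An \code{\link{eligibility_rule}}.
#' @param grouping \code{"continent"} or \code{"group_label"}.
#' @param seed Non-negative integer global seed (fans out to per-stage
#'   streams).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir,
                            affiliations = NULL, registry = NULL,
                            simulate = list(), world = list(),
                            window = 1998:2017,
                            nmr_periods = list(2000:2005, 2006:2011, 2012:2017),
                            rule = eligibility_rule(),
                            grouping = "continent",
                            seed = 1L) {
  if (length(window) < 1 || anyNA(window) || is.unsorted(window)) {
    stop("invalid analysis window (must be a nondecreasing year range)", call. = FALSE)
  }
  if (seed < 0) stop("seed must be non-negative", call. = FALSE)
  if (xor(is.null(affiliations), is.null(registry))) {
    stop("affiliations and registry paths must be given together", call. = FALSE)
  }
  if (!is.null(affiliations)) {
    for (p in c(affiliations, registry)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(list(
    out_dir = out_dir, affiliations = affiliations, registry = registry,
    simulate = simulate, world = world,
    window = as.integer(window), nmr_periods = nmr_periods,
    rule = rule, grouping = grouping, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   \code{\link{pipeline_config}} (\code{window} and period entries may be
#'   \code{"1998:2017"}-style strings).
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  parse_range <- function(v) {
    if (is.character(v)) {
      p <- as.integer(strsplit(v, ":", fixed = TRUE)[[1]])
      return(seq(p[1], p[2]))
    }
    as.integer(v)
  }
  args <- list(out_dir = y$out_dir %||% "out")
  if (!is.null(y$affiliations)) args$affiliations <- y$affiliations
  if (!is.null(y$registry)) args$registry <- y$registry
  if (!is.null(y$simulate)) args$simulate <- y$simulate
  if (!is.null(y$world)) args$world <- y$world
  if (!is.null(y$window)) args$window <- parse_range(y$window)
  if (!is.null(y$nmr_periods)) args$nmr_periods <- lapply(y$nmr_periods, parse_range)
  if (!is.null(y$rule)) args$rule <- do.call(eligibility_rule, y$rule)
  if (!is.null(y$grouping)) args$grouping <- y$grouping
  if (!is.null(y$seed)) args$seed <- as.integer(y$seed)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Schema-validated CSV reader: all columns must be present; file/line
# context is attached to the error.
read_table_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(columns, names(d))
  if (length(missing)) {
    stop(sprintf("%s: missing columns: %s", path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  d
}

#' Run the full migration-estimation pipeline
#'
#' Executes simulate (when no input files are configured) -> residence
#' inference -> censoring -> flow tabulation -> NMRs -> rates -> Gini
#' series -> per-region trends -> interrelation analysis, writes every
#' product as CSV under the configured output directory, and records a
#' manifest (config, seeds, row counts, file digests). Re-running with the
#' same configuration byte-reproduces all outputs.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Object of class \code{"migration_run"}: all intermediate and
#'   final tables plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(config$affiliations)) {
    world_args <- utils::modifyList(
      list(n_continents = 3L, countries_per_continent = 3L, regions_per_country = 4L,
           seed = config$seed),
      config$world)
    registry <- do.call(build_world, world_args)
    cc <- do.call(cohort_config, utils::modifyList(list(seed = config$seed), config$simulate))
    cohort <- simulate_cohort(registry, cc)
    records <- cohort$records
    write_cohort(cohort, registry, config$out_dir)
  } else {
    registry <- read_table_checked(config$registry,
                                   c("region_id", "country_id", "continent_id"))
    if (!"group_label" %in% names(registry)) registry$group_label <- registry$continent_id
    validate_registry(registry)
    records <- read_table_checked(config$affiliations,
                                  c("author_id", "year", "region_id", "country_id"))
    cohort <- NULL
  }

  inferred <- infer_residences(records, registry, seed = config$seed)
  cens <- censor_window(inferred$events, inferred$residences,
                        min(config$window), max(config$window))
  flows <- tabulate_flows(cens$residences, cens$events, registry)
  nmr <- do.call(rbind, c(
    lapply(config$nmr_periods, function(p) {
      do.call(rbind, lapply(c("total", "internal", "international"),
                            function(sc) period_nmr(flows, p, sc)))
    }),
    lapply(c("total", "internal", "international"),
           function(sc) annual_nmr(flows, sc))
  ))
  rates <- all_rates(flows)
  gini <- suppressWarnings(gini_series(rates, registry, config$grouping))
  trends <- region_trends(flows, config$window, config$rule)
  kendall <- region_tau_pairs(rates, config$window)
  inter <- if (nrow(trends)) {
    interrelate(trends, registry, config$grouping, seed = config$seed)
  } else {
    list(eiv = NULL, quadrants = NULL, fits = list())
  }

  paths <- c(
    residences = "residences.csv", events = "events.csv", flows = "flows.csv",
    nmr = "nmr.csv", rates = "rates.csv", gini = "gini.csv",
    trends = "trends.csv", kendall = "kendall.csv",
    eiv_fits = "eiv_fits.csv", quadrants = "quadrants.csv"
  )
  paths <- vapply(paths, function(p) file.path(config$out_dir, p), character(1))
  utils::write.csv(inferred$residences, paths["residences"], row.names = FALSE)
  utils::write.csv(inferred$events, paths["events"], row.names = FALSE)
  utils::write.csv(flows, paths["flows"], row.names = FALSE)
  utils::write.csv(nmr, paths["nmr"], row.names = FALSE)
  utils::write.csv(rates, paths["rates"], row.names = FALSE)
  utils::write.csv(gini, paths["gini"], row.names = FALSE)
  utils::write.csv(trends, paths["trends"], row.names = FALSE)
  utils::write.csv(kendall, paths["kendall"], row.names = FALSE)
  if (!is.null(inter$eiv)) utils::write.csv(inter$eiv, paths["eiv_fits"], row.names = FALSE)
  if (!is.null(inter$quadrants)) utils::write.csv(inter$quadrants, paths["quadrants"], row.names = FALSE)

  written <- paths[file.exists(paths)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("scholmig")),
    seed = config$seed,
    window = range(config$window),
    grouping = config$grouping,
    row_counts = list(
      records = nrow(records), residences = nrow(inferred$residences),
      events = nrow(inferred$events), flows = nrow(flows),
      gini = nrow(gini), trends = nrow(trends), kendall = nrow(kendall)
    ),
    digests = as.list(tools::md5sum(written))
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  out <- list(
    config = config, registry = registry, cohort = cohort,
    residences = inferred$residences, events = inferred$events,
    flows = flows, nmr = nmr, rates = rates, gini = gini,
    trends = trends, kendall = kendall, interrelation = inter,
    manifest = manifest, paths = written
  )
  class(out) <- "migration_run"
  out
}

#' @export
print.migration_run <- function(x, ...) {
  cat("Scholar migration pipeline run\n")
  cat(sprintf("  window: %d-%d   seed: %d   grouping: %s\n",
              x$manifest$window[1], x$manifest$window[2],
              x$manifest$seed, x$config$grouping))
  rc <- x$manifest$row_counts
  cat(sprintf("  records: %d   residences: %d   events: %d\n",
              rc$records, rc$residences, rc$events))
  cat(sprintf("  flows: %d rows   gini: %d   trends: %d   kendall: %d\n",
              rc$flows, rc$gini, rc$trends, rc$kendall))
  cat(sprintf("  outputs: %s\n", dirname(x$paths[1])))
  invisible(x)
}
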