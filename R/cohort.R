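#' Configuration for the synthetic scholar cohort simulator
#'
#' Bundles and validates the parameters that govern simulated publishing
#' careers and moves. Defaults emulate the regime of a large longitudinal
#' bibliometric panel: a 1996--2020 observation span, intermittent annual
#' publishing, occasional second same-year affiliations, and small
#' per-author-year move hazards with internal moves roughly twice as
#' frequent as international ones.
#'
#' @param n_authors Number of authors to simulate.
#' @param year_span Inclusive integer year range, default \code{1996:2020}.
#' @param career_start_range Years in which careers may start (first
#'   publication-activity year); default the whole span.
#' @param career_length_mean Mean career length in years; lengths are drawn
#'   as 1 + Poisson(career_length_mean - 1) and truncated at the end of the
#'   span.
#' @param publish_prob Probability an active author publishes in a year.
#' @param multi_affil_prob Probability a publishing author-year carries a
#'   second affiliation.
#' @param multi_affil_foreign_split Probability that the second affiliation
#'   is in a different country (otherwise: same country, different region).
#' @param internal_move_rate,international_move_rate Per-author-year move
#'   hazards (year-boundary moves); their sum must be <= 1.
#' @param region_trend Named numeric vector of per-region multiplicative
#'   annual changes in the move hazards of authors resident there
#'   (e.g. \code{c(C1.c1.r1 = 1.05)} for +5\%/yr); unnamed regions get 1.
#' @param seed Integer seed for the cohort random stream.
#' @return A list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_authors = 2000L,
                          year_span = 1996:2020,
                          career_start_range = NULL,
                          career_length_mean = 12,
                          publish_prob = 0.7,
                          multi_affil_prob = 0.1,
                          multi_affil_foreign_split = 0.5,
                          internal_move_rate = 0.03,
                          international_move_rate = 0.015,
                          region_trend = numeric(0),
                          seed = 1L) {
  if (length(year_span) < 1) stop("year_span must be non-empty", call. = FALSE)
  probs <- c(publish_prob, multi_affil_prob, multi_affil_foreign_split)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (internal_move_rate < 0 || international_move_rate < 0) {
    stop("move hazards must be non-negative", call. = FALSE)
  }
  if (internal_move_rate + international_move_rate > 1) {
    stop("internal_move_rate + international_move_rate must be <= 1", call. = FALSE)
  }
  if (is.null(career_start_range)) career_start_range <- range(year_span)
  structure(list(
    n_authors = as.integer(n_authors),
    year_span = as.integer(sort(year_span)),
    career_start_range = as.integer(career_start_range),
    career_length_mean = career_length_mean,
    publish_prob = publish_prob,
    multi_affil_prob = multi_affil_prob,
    multi_affil_foreign_split = multi_affil_foreign_split,
    internal_move_rate = internal_move_rate,
    international_move_rate = international_move_rate,
    region_trend = region_trend,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate a scholar cohort with known ground truth
#'
#' Generates author-level publication/affiliation histories on a region
#' registry. Each author gets a career span; in every active year the true
#' residence is a single region (moves happen at year boundaries, at most
#' once per author-year); publishing is intermittent (i.i.d. Bernoulli per
#' active year, with at least one record per author) and a publishing year
#' occasionally carries a second affiliation in another region or country,
#' which exercises modal tie-breaking downstream.
#'
#' @param registry A region registry from \code{\link{build_world}}.
#' @param config A \code{\link{cohort_config}}.
#' @return A list with components:
#'   \describe{
#'     \item{records}{data.frame of affiliation records
#'       (\code{author_id}, \code{year}, \code{region_id}, \code{country_id}).}
#'     \item{truth}{list with \code{residence} (true author-year residences),
#'       \code{events} (true migration events with scope), and \code{flows}
#'       (true per-region-year inflow/outflow tallies by scope).}
#'   }
#' @export
simulate_cohort <- function(registry, config = cohort_config()) {
  validate_registry(registry)
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "cohort"), simulate_cohort_impl(registry, config))
}

simulate_cohort_impl <- function(registry, config) {
  years <- config$year_span
  y0 <- years[1]
  region_country <- registry_lookup(registry, "country_id")
  regions <- registry$region_id
  countries <- unique(registry$country_id)
  regions_by_country <- split(regions, registry$country_id)

  trend <- rep(1, length(regions))
  names(trend) <- regions
  if (length(config$region_trend)) {
    trend[names(config$region_trend)] <- config$region_trend
  }

  rec_author <- list(); rec_year <- list(); rec_region <- list()
  res_author <- list(); res_year <- list(); res_region <- list()
  ev <- list()
  k <- 0L

  pick_other <- function(pool, exclude) {
    pool <- setdiff(pool, exclude)
    if (length(pool) == 0) return(NA_character_)
    pool[sample.int(length(pool), 1L)]
  }

  for (a in seq_len(config$n_authors)) {
    id <- sprintf("A%05d", a)
    start <- sample(seq(config$career_start_range[1], config$career_start_range[2]), 1L)
    len <- 1L + stats::rpois(1L, max(config$career_length_mean - 1, 0))
    end <- min(start + len - 1L, years[length(years)])
    active <- start:end
    cur <- regions[sample.int(length(regions), 1L)]

    res_path <- character(length(active))
    for (j in seq_along(active)) {
      t <- active[j]
      if (j > 1L) {
        f <- trend[[cur]]^(t - y0)
        p_int <- min(config$internal_move_rate * f, 1)
        p_itl <- min(config$international_move_rate * f, max(0, 1 - p_int))
        u <- stats::runif(1)
        dest <- NA_character_
        if (u < p_int) {
          dest <- pick_other(regions_by_country[[region_country[[cur]]]], cur)
          scope <- "internal"
        } else if (u < p_int + p_itl) {
          co <- pick_other(countries, region_country[[cur]])
          if (!is.na(co)) dest <- regions_by_country[[co]][sample.int(length(regions_by_country[[co]]), 1L)]
          scope <- "international"
        }
        if (!is.na(dest)) {
          k <- k + 1L
          ev[[k]] <- data.frame(
            author_id = id, year = t,
            origin_region = cur, origin_country = region_country[[cur]],
            dest_region = dest, dest_country = region_country[[dest]],
            scope = scope, stringsAsFactors = FALSE
          )
          cur <- dest
        }
      }
      res_path[j] <- cur
    }

    publishes <- stats::runif(length(active)) < config$publish_prob
    if (!any(publishes)) publishes[sample.int(length(active), 1L)] <- TRUE
    py <- active[publishes]
    pr <- res_path[publishes]
    # second affiliations: same-country other region or foreign region
    second <- stats::runif(length(py)) < config$multi_affil_prob
    sec_region <- rep(NA_character_, length(py))
    for (j in which(second)) {
      if (stats::runif(1) < config$multi_affil_foreign_split) {
        co <- pick_other(countries, region_country[[pr[j]]])
        if (!is.na(co)) sec_region[j] <- regions_by_country[[co]][sample.int(length(regions_by_country[[co]]), 1L)]
      } else {
        sec_region[j] <- pick_other(regions_by_country[[region_country[[pr[j]]]]], pr[j])
      }
    }
    keep <- !is.na(sec_region)
    rec_author[[a]] <- c(rep(id, length(py)), rep(id, sum(keep)))
    rec_year[[a]] <- c(py, py[keep])
    rec_region[[a]] <- c(pr, sec_region[keep])
    res_author[[a]] <- rep(id, length(active))
    res_year[[a]] <- active
    res_region[[a]] <- res_path
  }

  records <- data.frame(
    author_id = unlist(rec_author), year = unlist(rec_year),
    region_id = unlist(rec_region), stringsAsFactors = FALSE
  )
  records$country_id <- unname(region_country[records$region_id])
  o <- order(records$author_id, records$year, records$region_id)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL

  residence <- data.frame(
    author_id = unlist(res_author), year = unlist(res_year),
    region_id = unlist(res_region), stringsAsFactors = FALSE
  )
  residence$country_id <- unname(region_country[residence$region_id])
  rownames(residence) <- NULL

  events <- if (k > 0) do.call(rbind, ev) else data.frame(
    author_id = character(0), year = integer(0),
    origin_region = character(0), origin_country = character(0),
    dest_region = character(0), dest_country = character(0),
    scope = character(0), stringsAsFactors = FALSE
  )

  list(records = records, truth = list(
    residence = residence,
    events = events,
    flows = truth_flows(events)
  ))
}

# Tally true events into per-region-year inflow/outflow counts by scope.
truth_flows <- function(events) {
  if (nrow(events) == 0) {
    return(data.frame(region_id = character(0), year = integer(0), scope = character(0),
                      inflow = integer(0), outflow = integer(0), stringsAsFactors = FALSE))
  }
  inn <- stats::aggregate(list(inflow = rep(1L, nrow(events))),
                          by = list(region_id = events$dest_region, year = events$year,
                                    scope = events$scope), FUN = sum)
  out <- stats::aggregate(list(outflow = rep(1L, nrow(events))),
                          by = list(region_id = events$origin_region, year = events$year,
                                    scope = events$scope), FUN = sum)
  m <- merge(inn, out, by = c("region_id", "year", "scope"), all = TRUE)
  m$inflow[is.na(m$inflow)] <- 0L
  m$outflow[is.na(m$outflow)] <- 0L
  m[order(m$region_id, m$year, m$scope), , drop = FALSE]
}

#' Write a simulated cohort to CSV files
#'
#' Writes the affiliation table (\code{affiliations.csv}), the registry
#' (\code{registry.csv}) and the ground truth (\code{truth_residence.csv},
#' \code{truth_events.csv}) under \code{dir}.
#'
#' @param cohort Result of \code{\link{simulate_cohort}}.
#' @param registry The registry used to simulate.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    affiliations = file.path(dir, "affiliations.csv"),
    registry = file.path(dir, "registry.csv"),
    truth_residence = file.path(dir, "truth_residence.csv"),
    truth_events = file.path(dir, "truth_events.csv")
  )
  utils::write.csv(cohort$records, paths[["affiliations"]], row.names = FALSE)
  utils::write.csv(registry, paths[["registry"]], row.names = FALSE)
  utils::write.csv(cohort$truth$residence, paths[["truth_residence"]], row.names = FALSE)
  utils::write.csv(cohort$truth$events, paths[["truth_events"]], row.names = FALSE)
  invisible(paths)
}
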