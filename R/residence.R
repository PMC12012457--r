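#' Modal country of residence for one author-year
#'
#' The annual residence country is the mode of all affiliation countries
#' observed for the author in that year. Ties are broken in favour of the
#' tied country that appears in the closest previous residence year; if no
#' tied country has been seen before, one is chosen uniformly at random
#' (from the caller's seeded random stream).
#'
#' @param countries Character vector (multiset) of the year's affiliation
#'   countries.
#' @param prior Character vector of the author's previous modal countries,
#'   most recent first (may be empty).
#' @return A single country identifier.
#' @export
modal_country <- function(countries, prior = character(0)) {
  if (length(countries) == 0) stop("year_affiliations must be non-empty", call. = FALSE)
  tab <- table(countries)
  tied <- names(tab)[tab == max(tab)]
  pick_mode(tied, prior)
}

#' Modal region of residence within the modal country
#'
#' The region mode is taken hierarchically: only the year's affiliations in
#' the already-decided modal country are considered, which guarantees the
#' region residence is consistent with the country residence. Tie rules are
#' the same as for \code{\link{modal_country}}.
#'
#' @param regions Character vector of the year's affiliation regions.
#' @param countries Parallel character vector of their countries.
#' @param country The modal country decided for this year.
#' @param prior Character vector of the author's previous modal regions,
#'   most recent first.
#' @return A single region identifier.
#' @export
modal_region <- function(regions, countries, country, prior = character(0)) {
  keep <- countries == country
  if (!any(keep)) {
    stop("internal inconsistency: no affiliation in the modal country", call. = FALSE)
  }
  tab <- table(regions[keep])
  tied <- names(tab)[tab == max(tab)]
  pick_mode(tied, prior)
}

# Shared tie-break: closest previous residence wins; all-new ties are
# resolved uniformly at random from the current RNG stream.
pick_mode <- function(tied, prior) {
  if (length(tied) == 1L) return(tied)
  for (p in prior) if (p %in% tied) return(p)
  tied[sample.int(length(tied), 1L)]
}

#' Build the annual residence timeline of one author
#'
#' Computes the modal country and region for every observed publication
#' year, then applies the two-year backward fill: a publication gap of
#' length g >= 1 before an observed year y fills years y-1 and y-2 (at most
#' min(g, 2) years) with y's residence, reflecting a two-year publication
#' preparation time, without ever overwriting an observed year. Gap years
#' more than two years before the next observation remain unassigned.
#'
#' @param records data.frame of one author's affiliation records with
#'   columns \code{year}, \code{region_id}, \code{country_id}.
#' @return data.frame with columns \code{year}, \code{region_id},
#'   \code{country_id}, \code{source} (\code{"observed"} or
#'   \code{"backfilled"}), sorted by year, one row per year.
#' @export
build_residence_timeline <- function(records) {
  if (nrow(records) == 0) stop("records must be non-empty", call. = FALSE)
  yrs <- sort(unique(records$year))
  res_country <- character(0)  # most recent first
  res_region <- character(0)
  out_year <- integer(length(yrs))
  out_region <- character(length(yrs))
  out_country <- character(length(yrs))
  for (j in seq_along(yrs)) {
    y <- yrs[j]
    rows <- records[records$year == y, , drop = FALSE]
    co <- modal_country(rows$country_id, res_country)
    re <- modal_region(rows$region_id, rows$country_id, co, res_region)
    out_year[j] <- y
    out_country[j] <- co
    out_region[j] <- re
    res_country <- c(co, res_country)
    res_region <- c(re, res_region)
  }
  obs <- data.frame(year = out_year, region_id = out_region,
                    country_id = out_country, source = "observed",
                    stringsAsFactors = FALSE)
  # backward fill interior gaps by up to two years
  fills <- vector("list", length(yrs))
  for (j in seq_along(yrs)[-1]) {
    gap <- yrs[j] - yrs[j - 1L] - 1L
    if (gap >= 1L) {
      fy <- seq(yrs[j] - min(gap, 2L), yrs[j] - 1L)
      fills[[j]] <- data.frame(year = fy, region_id = out_region[j],
                               country_id = out_country[j], source = "backfilled",
                               stringsAsFactors = FALSE)
    }
  }
  out <- rbind(obs, do.call(rbind, fills))
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect migration events in a residence timeline
#'
#' A migration event is recorded whenever the region of residence differs
#' between two consecutive residence years; the migration year is the first
#' year carrying the new residence. An event between regions of the same
#' country is internal; between regions of different countries,
#' international.
#'
#' @param timeline One author's residence timeline
#'   (\code{\link{build_residence_timeline}} output), sorted and
#'   duplicate-free.
#' @param registry Optional registry; if supplied, timeline regions are
#'   checked against it.
#' @return data.frame of events with columns \code{year},
#'   \code{origin_region}, \code{origin_country}, \code{dest_region},
#'   \code{dest_country}, \code{scope}.
#' @export
detect_migration_events <- function(timeline, registry = NULL) {
  if (!is.null(registry)) {
    lk <- registry_lookup(registry, "country_id")
    if (any(!timeline$region_id %in% names(lk)) ||
        any(lk[timeline$region_id] != timeline$country_id)) {
      stop("timeline regions inconsistent with registry", call. = FALSE)
    }
  }
  n <- nrow(timeline)
  empty <- data.frame(year = integer(0), origin_region = character(0),
                      origin_country = character(0), dest_region = character(0),
                      dest_country = character(0), scope = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  i <- which(timeline$region_id[-1L] != timeline$region_id[-n]) + 1L
  if (length(i) == 0L) return(empty)
  data.frame(
    year = timeline$year[i],
    origin_region = timeline$region_id[i - 1L],
    origin_country = timeline$country_id[i - 1L],
    dest_region = timeline$region_id[i],
    dest_country = timeline$country_id[i],
    scope = ifelse(timeline$country_id[i] == timeline$country_id[i - 1L],
                   "internal", "international"),
    stringsAsFactors = FALSE
  )
}

#' Infer residences and migration events for a whole affiliation table
#'
#' Applies \code{\link{build_residence_timeline}} and
#' \code{\link{detect_migration_events}} author by author, in a single
#' seeded random stream so modal tie-breaks are reproducible run to run.
#'
#' @param records Affiliation table (\code{author_id}, \code{year},
#'   \code{region_id}, \code{country_id}).
#' @param registry Optional registry for consistency checks.
#' @param seed Integer seed for the tie-break stream.
#' @return list with \code{residences} (adds \code{author_id} and
#'   \code{source}) and \code{events} (adds \code{author_id}).
#' @export
infer_residences <- function(records, registry = NULL, seed = 1L) {
  stopifnot(all(c("author_id", "year", "region_id", "country_id") %in% names(records)))
  with_seed(derive_seed(seed, "ties"), {
    by_author <- split(records, records$author_id)
    res <- vector("list", length(by_author))
    evs <- vector("list", length(by_author))
    ids <- names(by_author)
    for (j in seq_along(by_author)) {
      tl <- build_residence_timeline(by_author[[j]])
      ee <- detect_migration_events(tl, registry)
      res[[j]] <- cbind(author_id = ids[j], tl, stringsAsFactors = FALSE)
      if (nrow(ee)) evs[[j]] <- cbind(author_id = ids[j], ee, stringsAsFactors = FALSE)
    }
    residences <- do.call(rbind, res)
    rownames(residences) <- NULL
    events <- do.call(rbind, evs)
    if (is.null(events)) {
      events <- data.frame(author_id = character(0), year = integer(0),
                           origin_region = character(0), origin_country = character(0),
                           dest_region = character(0), dest_country = character(0),
                           scope = character(0), stringsAsFactors = FALSE)
    }
    rownames(events) <- NULL
    list(residences = residences, events = events)
  })
}

#' Restrict residences and events to an analysis window
#'
#' Drops rows outside the inclusive year window. The default 1998--2017
#' window trims the first and last years of a 1996--2020 panel, limiting
#' left- and right-censoring artifacts (residences before the window cannot
#' be observed, so early event years are undercounted; symmetric logic at
#' the right edge with the backward fill).
#'
#' @param events Events table with a \code{year} column.
#' @param residences Residences table with a \code{year} column.
#' @param first_year,last_year Inclusive window bounds.
#' @return list with filtered \code{events} and \code{residences}.
#' @export
censor_window <- function(events, residences, first_year = 1998L, last_year = 2017L) {
  if (first_year > last_year) stop("inverted window: first_year > last_year", call. = FALSE)
  list(
    events = events[events$year >= first_year & events$year <= last_year, , drop = FALSE],
    residences = residences[residences$year >= first_year & residences$year <= last_year, , drop = FALSE]
  )
}
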