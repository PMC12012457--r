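#' Tabulate region-year scholar populations and migration flows
#'
#' Aggregates residences into per-region-year scholar populations N and
#' events into directional flow counts by scope. Every event increments
#' exactly one outflow cell (origin region, event year) and one inflow cell
#' (destination region, event year). The table covers all registry regions
#' crossed with all residence years; region-years with N = 0 are kept and
#' flagged (\code{defined = FALSE}) rather than treated as zero rates.
#'
#' @param residences Residence table (\code{author_id}, \code{year},
#'   \code{region_id}, ...).
#' @param events Events table (\code{year}, \code{origin_region},
#'   \code{dest_region}, \code{scope}).
#' @param registry Region registry; events referencing unknown regions are
#'   an error.
#' @return data.frame with columns \code{region_id}, \code{year}, \code{N},
#'   \code{I_internal}, \code{I_international}, \code{E_internal},
#'   \code{E_international}, \code{I_total}, \code{E_total}, \code{defined}.
#' @export
tabulate_flows <- function(residences, events, registry) {
  validate_registry(registry)
  bad <- setdiff(unique(c(events$origin_region, events$dest_region)), registry$region_id)
  if (length(bad)) {
    stop("events reference unknown regions: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  years <- sort(unique(residences$year))
  if (length(years) == 0) stop("residences table is empty", call. = FALSE)
  regions <- registry$region_id
  grid <- expand.grid(region_id = regions, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  cell <- function(region, year) match(region, regions) + (match(year, years) - 1L) * length(regions)
  N <- integer(nrow(grid))
  tab <- table(cell(residences$region_id, residences$year))
  N[as.integer(names(tab))] <- as.integer(tab)

  count_into <- function(region_col, scope_name) {
    v <- integer(nrow(grid))
    sel <- events$scope == scope_name & events$year %in% years
    if (any(sel)) {
      tt <- table(cell(events[[region_col]][sel], events$year[sel]))
      v[as.integer(names(tt))] <- as.integer(tt)
    }
    v
  }
  grid$N <- N
  grid$I_internal <- count_into("dest_region", "internal")
  grid$I_international <- count_into("dest_region", "international")
  grid$E_internal <- count_into("origin_region", "internal")
  grid$E_international <- count_into("origin_region", "international")
  grid$I_total <- grid$I_internal + grid$I_international
  grid$E_total <- grid$E_internal + grid$E_international
  grid$defined <- grid$N > 0L
  grid[order(grid$region_id, grid$year), , drop = FALSE]
}

scope_cols <- function(scope = c("total", "internal", "international")) {
  scope <- match.arg(scope)
  c(I = paste0("I_", scope), E = paste0("E_", scope))
}

#' Annual net migration rate per 1,000 scholars
#'
#' NMR = 1000 x (inflow - outflow) / N for each region-year, for the
#' requested scope (internal, international, or total). Region-years with
#' N = 0 yield an undefined rate (NA, \code{defined = FALSE}); they are
#' flagged, not silently dropped, because 0/0 is not evidence of zero
#' migration.
#'
#' @param flows Output of \code{\link{tabulate_flows}}.
#' @param scope One of \code{"total"}, \code{"internal"},
#'   \code{"international"}.
#' @return data.frame \code{region_id}, \code{period_start},
#'   \code{period_end}, \code{scope}, \code{nmr_per_1000}, \code{defined}.
#' @export
annual_nmr <- function(flows, scope = c("total", "internal", "international")) {
  scope <- match.arg(scope)
  sc <- scope_cols(scope)
  out <- data.frame(
    region_id = flows$region_id,
    period_start = flows$year, period_end = flows$year,
    scope = scope,
    nmr_per_1000 = ifelse(flows$N > 0,
                          1000 * (flows[[sc["I"]]] - flows[[sc["E"]]]) / flows$N,
                          NA_real_),
    defined = flows$N > 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Period-averaged net migration rate
#'
#' NMR over a multi-year period: 1000 x (sum of inflows - sum of outflows)
#' divided by the summed scholar population over the period. Because
#' person-years accumulate in the denominator, the result is automatically
#' a per-year rate. A region is considered present in the period if it has
#' scholars in any year of it; otherwise the rate is undefined.
#'
#' @param flows Output of \code{\link{tabulate_flows}}.
#' @param period Inclusive integer year range, e.g. \code{2012:2017}.
#' @param scope Migration scope as in \code{\link{annual_nmr}}.
#' @return One row per region: \code{region_id}, \code{period_start},
#'   \code{period_end}, \code{scope}, \code{nmr_per_1000}, \code{defined}.
#' @export
period_nmr <- function(flows, period, scope = c("total", "internal", "international")) {
  scope <- match.arg(scope)
  sc <- scope_cols(scope)
  f <- flows[flows$year %in% period, , drop = FALSE]
  agg <- stats::aggregate(f[, c("N", sc["I"], sc["E"])],
                          by = list(region_id = f$region_id), FUN = sum)
  out <- data.frame(
    region_id = agg$region_id,
    period_start = min(period), period_end = max(period),
    scope = scope,
    nmr_per_1000 = ifelse(agg$N > 0,
                          1000 * (agg[[sc["I"]]] - agg[[sc["E"]]]) / agg$N,
                          NA_real_),
    defined = agg$N > 0,
    stringsAsFactors = FALSE
  )
  out[order(out$region_id), , drop = FALSE]
}

#' Annual directional migration rates
#'
#' Migration rate = count of migration events divided by the number of
#' scholars, per region-year, for one direction (in or out) and scope.
#' These unitless per-scholar-year rates feed the inequality and rank
#' correlation analyses.
#'
#' @param flows Output of \code{\link{tabulate_flows}}.
#' @param direction \code{"in"} or \code{"out"}.
#' @param scope \code{"total"}, \code{"internal"} or \code{"international"}.
#' @return data.frame \code{region_id}, \code{year}, \code{N},
#'   \code{count}, \code{rate}, \code{direction}, \code{scope},
#'   \code{defined}.
#' @export
annual_rates <- function(flows, direction = c("in", "out"),
                         scope = c("total", "internal", "international")) {
  direction <- match.arg(direction)
  scope <- match.arg(scope)
  col <- paste0(if (direction == "in") "I_" else "E_", scope)
  out <- data.frame(
    region_id = flows$region_id, year = flows$year, N = flows$N,
    count = flows[[col]],
    rate = ifelse(flows$N > 0, flows[[col]] / flows$N, NA_real_),
    direction = direction, scope = scope,
    defined = flows$N > 0,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' All six directional rate series
#'
#' Stacks \code{\link{annual_rates}} over the six migration types
#' (internal/international/total crossed with in/out), labelling each row
#' with \code{migration_type} (e.g. \code{"internal-in"}).
#'
#' @param flows Output of \code{\link{tabulate_flows}}.
#' @return Long data.frame of rates for all six types.
#' @export
all_rates <- function(flows) {
  out <- do.call(rbind, lapply(c("internal", "international", "total"), function(sc) {
    do.call(rbind, lapply(c("in", "out"), function(d) annual_rates(flows, d, sc)))
  }))
  out$migration_type <- paste0(out$scope, "-", out$direction)
  rownames(out) <- NULL
  out
}
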