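#' Build a synthetic world region registry
#'
#' Constructs a balanced three-level administrative hierarchy
#' (continent > country > first-level subnational region) emulating the
#' Admin-1 geography used for subnational migration accounting. Labels are
#' opaque (\code{"C1"}, \code{"C1.c2"}, \code{"C1.c2.r3"}) and globally
#' unique; every region maps to exactly one country and every country to
#' exactly one continent.
#'
#' @param n_continents Number of continents (>= 1).
#' @param countries_per_continent Countries per continent (>= 1).
#' @param regions_per_country Regions per country (>= 1).
#' @param seed Integer seed; used only to assign the optional random
#'   \code{group_label} (an alternative grouping such as an income class).
#' @param n_groups Number of alternative group labels to assign countries to
#'   (all regions of a country share its group).
#' @return A data.frame with columns \code{region_id}, \code{country_id},
#'   \code{continent_id}, \code{group_label}.
#' @examples
#' reg <- build_world(2, 3, 4, seed = 1)
#' nrow(reg)  # 24
#' @export
build_world <- function(n_continents, countries_per_continent, regions_per_country,
                        seed = 1L, n_groups = 3L) {
  for (v in c(n_continents, countries_per_continent, regions_per_country)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v)) {
      stop("all counts must be positive integers", call. = FALSE)
    }
  }
  continent <- sprintf("C%d", seq_len(n_continents))
  country <- as.vector(outer(seq_len(countries_per_continent), continent,
                             function(k, cc) sprintf("%s.c%d", cc, k)))
  country_continent <- rep(continent, each = countries_per_continent)
  region <- as.vector(outer(seq_len(regions_per_country), country,
                            function(r, co) sprintf("%s.r%d", co, r)))
  reg <- data.frame(
    region_id = region,
    country_id = rep(country, each = regions_per_country),
    continent_id = rep(country_continent, each = regions_per_country),
    stringsAsFactors = FALSE
  )
  group_by_country <- with_seed(derive_seed(seed, "world"), {
    stats::setNames(sprintf("G%d", sample.int(n_groups, length(country), replace = TRUE)),
                    country)
  })
  reg$group_label <- unname(group_by_country[reg$country_id])
  validate_registry(reg)
  reg
}

#' Validate a region registry
#'
#' Checks the hierarchy invariants: globally unique region identifiers,
#' each region in exactly one country, each country in exactly one
#' continent.
#'
#' @param registry A registry data.frame (\code{region_id}, \code{country_id},
#'   \code{continent_id}, optional \code{group_label}).
#' @return The registry, invisibly, if valid; otherwise an error.
#' @export
validate_registry <- function(registry) {
  need <- c("region_id", "country_id", "continent_id")
  if (!is.data.frame(registry) || !all(need %in% names(registry))) {
    stop("registry must have columns region_id, country_id, continent_id", call. = FALSE)
  }
  if (nrow(registry) == 0) stop("registry is empty", call. = FALSE)
  if (anyDuplicated(registry$region_id)) {
    stop("region_id values must be globally unique", call. = FALSE)
  }
  cc <- unique(registry[, c("country_id", "continent_id")])
  if (anyDuplicated(cc$country_id)) {
    stop("each country_id must map to exactly one continent_id", call. = FALSE)
  }
  invisible(registry)
}

# region -> country and region -> continent lookup vectors
registry_lookup <- function(registry, to = c("country_id", "continent_id", "group_label")) {
  to <- match.arg(to)
  stats::setNames(registry[[to]], registry$region_id)
}
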