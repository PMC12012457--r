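#' Eligibility rule for per-region trend estimation
#'
#' Regions enter the trend analysis only if they have more than
#' \code{min_peak_scholars} scholars in at least one observation year, at
#' least \code{min_obs_years} observation years, and at least
#' \code{min_nonzero_years} years with a nonzero migration count. The
#' default parsing treats these as three conjunctive conditions
#' (\code{parse = "conjunctive"}); the alternative reading --
#' \code{min_obs_years} years each with at least \code{min_nonzero_years}
#' events -- is available as \code{parse = "joint"}.
#'
#' @param min_peak_scholars Peak-population threshold (strict: "more
#'   than"), default 25.
#' @param min_obs_years Minimum observation years, default 10.
#' @param min_nonzero_years Minimum years with nonzero counts, default 5.
#' @param parse \code{"conjunctive"} or \code{"joint"}.
#' @return list of class \code{"eligibility_rule"}.
#' @export
eligibility_rule <- function(min_peak_scholars = 25L, min_obs_years = 10L,
                             min_nonzero_years = 5L,
                             parse = c("conjunctive", "joint")) {
  parse <- match.arg(parse)
  stopifnot(min_peak_scholars >= 1, min_obs_years >= 1, min_nonzero_years >= 1)
  structure(list(min_peak_scholars = min_peak_scholars,
                 min_obs_years = min_obs_years,
                 min_nonzero_years = min_nonzero_years,
                 parse = parse),
            class = "eligibility_rule")
}

#' Select regions eligible for trend estimation
#'
#' Applies an \code{\link{eligibility_rule}} to a flow table, optionally
#' for one specific count series (direction x scope); with no series given,
#' the nonzero-count condition uses total events (in + out, all scopes).
#' Observation years are region-years with scholars present (N > 0).
#'
#' @param flows Output of \code{\link{tabulate_flows}}.
#' @param rule An \code{\link{eligibility_rule}}.
#' @param direction Optional \code{"in"} or \code{"out"}.
#' @param scope Optional \code{"internal"}, \code{"international"},
#'   \code{"total"}.
#' @return Character vector of eligible region identifiers.
#' @export
eligible_regions <- function(flows, rule = eligibility_rule(),
                             direction = NULL, scope = NULL) {
  stopifnot(inherits(rule, "eligibility_rule"))
  if (is.null(direction) || is.null(scope)) {
    cnt <- flows$I_total + flows$E_total
  } else {
    cnt <- flows[[paste0(if (direction == "in") "I_" else "E_", scope)]]
  }
  obs <- flows$N > 0
  ok <- vapply(split(seq_len(nrow(flows)), flows$region_id), function(i) {
    peak <- max(flows$N[i]) > rule$min_peak_scholars
    n_obs <- sum(obs[i])
    if (rule$parse == "conjunctive") {
      peak && n_obs >= rule$min_obs_years &&
        sum(cnt[i] > 0 & obs[i]) >= rule$min_nonzero_years
    } else {
      peak && sum(cnt[i] >= rule$min_nonzero_years & obs[i]) >= rule$min_obs_years
    }
  }, logical(1))
  names(ok)[ok]
}

#' Fit a quasi-Poisson log-linear time trend with exposure offset
#'
#' Models per-year migration counts as E[count_t] = N_t exp(a + b t) via a
#' Poisson log-link GLM with offset log(N_t) (so the modelled quantity is a
#' rate), and inflates standard errors by the Pearson-based quasi-Poisson
#' dispersion phi = Pearson chi^2 / (n - 2) to accommodate overdispersion.
#' The time covariate is centered at the window midpoint for numerical
#' stability (the slope is unchanged). Years with zero exposure are
#' dropped.
#'
#' @param counts Integer event counts per year.
#' @param exposures Scholar populations N_t per year (exposure).
#' @param years Calendar years (same length).
#' @return Object of class \code{"qp_trend"} with elements \code{slope}
#'   (per-year change on the log scale), \code{se}, \code{dispersion},
#'   \code{intercept}, \code{n_years}, \code{slope_pct_per_year}, and the
#'   underlying \code{glm} fit.
#' @examples
#' t <- 0:19
#' fit <- fit_qp_trend(round(100 * exp(0.05 * t)), rep(1e4, 20), 1998 + t)
#' coef(fit)
#' @export
fit_qp_trend <- function(counts, exposures, years) {
  stopifnot(length(counts) == length(exposures), length(counts) == length(years))
  use <- exposures > 0 & !is.na(counts)
  counts <- counts[use]; exposures <- exposures[use]; years <- years[use]
  if (length(counts) < 3) stop("need at least 3 usable years", call. = FALSE)
  if (all(counts == 0)) stop("all counts are zero: no information about a trend", call. = FALSE)
  tc <- years - mean(range(years))
  fit <- stats::glm(counts ~ tc + offset(log(exposures)),
                    family = stats::quasipoisson(link = "log"),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("quasi-Poisson IRLS did not converge", call. = FALSE)
  sm <- summary(fit)
  out <- list(
    slope = unname(stats::coef(fit)["tc"]),
    se = unname(sm$coefficients["tc", "Std. Error"]),
    dispersion = sm$dispersion,
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    n_years = length(counts),
    years = years,
    glm = fit
  )
  out$slope_pct_per_year <- transform_slope(out$slope)
  class(out) <- "qp_trend"
  out
}

#' @export
print.qp_trend <- function(x, ...) {
  cat("Quasi-Poisson log-linear trend (offset: log exposure)\n")
  cat(sprintf("  years: %d (%d-%d)\n", x$n_years, min(x$years), max(x$years)))
  cat(sprintf("  slope: %.5f (se %.5f)  =  %+.2f%% per year\n",
              x$slope, x$se, x$slope_pct_per_year))
  cat(sprintf("  dispersion: %.3f\n", x$dispersion))
  invisible(x)
}

#' @export
coef.qp_trend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.qp_trend <- function(object, ...) {
  data.frame(slope = object$slope, se = object$se,
             dispersion = object$dispersion, n_years = object$n_years,
             slope_pct_per_year = object$slope_pct_per_year)
}

#' @export
confint.qp_trend <- function(object, parm = "slope", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = object$slope - z * object$se, upper = object$slope + z * object$se)
}

#' Slope-to-percent-change axis transform
#'
#' Maps a log-linear trend slope x to the proportional change per year,
#' T(x) = 100 (exp(x) - 1): T(0) = 0 means no change, T(0.1823) is a 20
#' percent annual increase, T(-0.2231) a 20 percent annual decrease.
#'
#' @param x Slope(s) on the linear-predictor (log) scale.
#' @return Percent change per year.
#' @export
transform_slope <- function(x) {
  stopifnot(all(is.finite(x)))
  100 * (exp(x) - 1)
}

#' Per-region trend estimates for all four directional series
#'
#' Fits \code{\link{fit_qp_trend}} per region for each direction (in/out)
#' and scope (internal/international), restricted to the analysis window
#' and to regions passing the eligibility rule for that series. Regions
#' whose fit fails (all-zero counts after filtering) are dropped.
#'
#' @param flows Output of \code{\link{tabulate_flows}}.
#' @param window Inclusive year range, default \code{1998:2017}.
#' @param rule An \code{\link{eligibility_rule}}.
#' @return data.frame \code{region_id}, \code{direction}, \code{scope},
#'   \code{slope}, \code{se}, \code{dispersion}, \code{n_years},
#'   \code{slope_pct_per_year}, \code{size_class}.
#' @export
region_trends <- function(flows, window = 1998:2017, rule = eligibility_rule()) {
  f <- flows[flows$year %in% window, , drop = FALSE]
  rows <- list()
  for (scope in c("internal", "international")) {
    for (direction in c("in", "out")) {
      elig <- eligible_regions(f, rule, direction, scope)
      col <- paste0(if (direction == "in") "I_" else "E_", scope)
      for (r in elig) {
        i <- which(f$region_id == r)
        fit <- tryCatch(fit_qp_trend(f[[col]][i], f$N[i], f$year[i]),
                        error = function(e) NULL)
        if (is.null(fit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = r, direction = direction, scope = scope,
          slope = fit$slope, se = fit$se, dispersion = fit$dispersion,
          n_years = fit$n_years, slope_pct_per_year = fit$slope_pct_per_year,
          size_class = as.character(size_class(max(f$N[i]))),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_id = character(0), direction = character(0),
                      scope = character(0), slope = numeric(0), se = numeric(0),
                      dispersion = numeric(0), n_years = integer(0),
                      slope_pct_per_year = numeric(0), size_class = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Reporting size classes by peak scholar population in the window.
size_class <- function(max_n) {
  cut(max_n, breaks = c(-Inf, 100, 1000, Inf),
      labels = c("0-100", "100-1,000", ">1,000"))
}
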