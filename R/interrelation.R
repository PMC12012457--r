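#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall coefficient between two equal-length series,
#' computed from concordant/discordant pair counts. The tie-corrected
#' variant matters here because annual migration rates contain ties at
#' zero, especially in small regions. Returns NA (with a flag-worthy
#' warning) when either series is constant, in which case ranking carries
#' no information.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Coefficient in [-1, 1], or NA if undefined.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant series: Kendall tau undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "kendall")
}

#' Per-region Kendall correlations between internal and international rates
#'
#' For each region, correlates the annual internal and international
#' in-migration rate series (tau_in) and the corresponding out-migration
#' series (tau_out) over the analysis window. Years without scholars are
#' excluded; regions where a tau is undefined (constant series or too few
#' years) are flagged.
#'
#' @param rates Long rate table from \code{\link{all_rates}}.
#' @param window Inclusive year range, default \code{1998:2017}.
#' @param min_years Minimum usable years per region, default 3.
#' @return data.frame \code{region_id}, \code{tau_in}, \code{tau_out},
#'   \code{n_years}, \code{defined}.
#' @export
region_tau_pairs <- function(rates, window = 1998:2017, min_years = 3L) {
  r <- rates[rates$year %in% window & rates$defined, , drop = FALSE]
  tau_one <- function(rr, direction) {
    a <- rr[rr$scope == "internal" & rr$direction == direction, c("year", "rate")]
    b <- rr[rr$scope == "international" & rr$direction == direction, c("year", "rate")]
    m <- merge(a, b, by = "year")
    if (nrow(m) < min_years) return(c(NA_real_, nrow(m)))
    tau <- suppressWarnings(kendall_tau(m$rate.x, m$rate.y))
    c(tau, nrow(m))
  }
  out <- do.call(rbind, lapply(split(r, r$region_id), function(rr) {
    ti <- tau_one(rr, "in")
    to <- tau_one(rr, "out")
    data.frame(region_id = rr$region_id[1], tau_in = ti[1], tau_out = to[1],
               n_years = as.integer(min(ti[2], to[2])), stringsAsFactors = FALSE)
  }))
  out$defined <- is.finite(out$tau_in) & is.finite(out$tau_out)
  rownames(out) <- NULL
  out
}

#' Quadrant fractions of a scatter of signed estimates
#'
#' Percentages of points in the four open quadrants; points with a zero
#' coordinate land in a separate on-axis bucket, so the four quadrant
#' percentages need not sum to 100 (quadrants + on-axis always do).
#'
#' @param x,y Numeric coordinates (e.g. international and internal trend
#'   slopes).
#' @return Named numeric vector: \code{upper_right} (x>0, y>0),
#'   \code{upper_left} (x<0, y>0), \code{lower_left} (x<0, y<0),
#'   \code{lower_right} (x>0, y<0), \code{on_axis}; in percent.
#' @export
quadrant_fractions <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0) stop("need at least one point", call. = FALSE)
  n <- length(x)
  c(upper_right = 100 * sum(x > 0 & y > 0) / n,
    upper_left = 100 * sum(x < 0 & y > 0) / n,
    lower_left = 100 * sum(x < 0 & y < 0) / n,
    lower_right = 100 * sum(x > 0 & y < 0) / n,
    on_axis = 100 * sum(x == 0 | y == 0) / n)
}

#' Bayesian errors-in-variables linear regression
#'
#' Regresses noisy y on noisy x when both carry known measurement standard
#' errors (here: internal-trend slopes on international-trend slopes, with
#' their quasi-Poisson SEs). The latent-variable model is
#' \deqn{x_i \sim N(\xi_i, sx_i^2), \quad y_i \sim N(\alpha + \beta \xi_i, sy_i^2 + \sigma^2)}
#' with weakly informative priors alpha, beta ~ N(0, 10^2) and sigma ~
#' half-N(0, 5). The latent xi are modelled hierarchically (structural
#' errors-in-variables): xi_i ~ N(mu_xi, tau^2), with a wide Normal prior
#' on mu_xi and a weakly informative inverse-gamma prior on tau^2 scaled to
#' the observed x variance. Learning tau from the data is what
#' de-attenuates the slope relative to naive least squares on the observed
#' x. Sampling is Gibbs for xi, (alpha, beta), mu_xi and tau^2, with a
#' random-walk Metropolis step (adapted during warm-up) for sigma. The
#' slope is significant when the central 95\% credible interval excludes
#' zero.
#'
#' @param y,y_se Response values and their standard errors.
#' @param x,x_se Predictor values and their standard errors.
#' @param chains Number of chains, default 4.
#' @param iter Post-warm-up draws per chain, default 2000.
#' @param warmup Warm-up iterations per chain, default 1000.
#' @param seed Integer seed.
#' @param level Credible level, default 0.95.
#' @return Object of class \code{"eiv_fit"}: posterior means
#'   (\code{intercept}, \code{slope}, \code{sigma}), \code{ci} for the
#'   slope, \code{significant}, \code{n}, draw matrices, and diagnostics
#'   (split-Rhat, effective sample size, Metropolis acceptance rate).
#' @export
fit_eiv <- function(y, y_se, x, x_se, chains = 4L, iter = 2000L, warmup = 1000L,
                    seed = 1L, level = 0.95) {
  n <- length(y)
  stopifnot(length(y_se) == n, length(x) == n, length(x_se) == n)
  if (n < 5) stop("need at least 5 observations", call. = FALSE)
  if (any(!is.finite(c(y, y_se, x, x_se)))) stop("non-finite inputs", call. = FALSE)
  if (any(y_se <= 0) || any(x_se <= 0)) stop("all SEs must be positive", call. = FALSE)

  prior_sd_ab <- 10
  prior_sd_sigma <- 5
  prior_sd_mu <- 10 * max(stats::sd(x), 1e-3)  # wide prior on the latent mean
  tau_a0 <- 1
  tau_b0 <- 0.5 * max(stats::var(x), 1e-6)     # weakly informative, x-scaled
  xs2 <- x_se^2
  ys2 <- y_se^2

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    alpha <- stats::rnorm(1, 0, 0.1)
    beta <- stats::rnorm(1, 0, 0.1)
    sigma <- abs(stats::rnorm(1, 0, 0.5)) + 0.01
    xi <- x
    mu_xi <- mean(x)
    tau2 <- max(stats::var(x) - mean(xs2), 0.1 * stats::var(x))
    step <- 0.5
    acc <- 0L
    warm_acc <- 0L
    total <- warmup + iter
    draws <- matrix(NA_real_, iter, 3, dimnames = list(NULL, c("alpha", "beta", "sigma")))
    log_post_sigma <- function(sig, alpha, beta, xi) {
      v <- ys2 + sig^2
      -0.5 * sum(log(v) + (y - alpha - beta * xi)^2 / v) -
        sig^2 / (2 * prior_sd_sigma^2)
    }
    for (s in seq_len(total)) {
      v <- ys2 + sigma^2
      # latent xi | rest (conjugate normal)
      prec <- 1 / xs2 + beta^2 / v + 1 / tau2
      mu <- (x / xs2 + beta * (y - alpha) / v + mu_xi / tau2) / prec
      xi <- stats::rnorm(n, mu, 1 / sqrt(prec))
      # latent-mean and latent-scale hyperparameters (conjugate)
      pm <- n / tau2 + 1 / prior_sd_mu^2
      mu_xi <- stats::rnorm(1, (sum(xi) / tau2 + mean(x) / prior_sd_mu^2) / pm,
                            1 / sqrt(pm))
      tau2 <- (tau_b0 + 0.5 * sum((xi - mu_xi)^2)) /
        stats::rgamma(1, tau_a0 + n / 2)
      # (alpha, beta) | rest: weighted Bayesian linear regression
      w <- 1 / v
      sw <- sum(w); swx <- sum(w * xi); swxx <- sum(w * xi^2)
      P <- matrix(c(sw, swx, swx, swxx), 2) + diag(2) / prior_sd_ab^2
      b <- c(sum(w * y), sum(w * xi * y))
      U <- chol(P)
      mean_ab <- backsolve(U, forwardsolve(t(U), b))
      ab <- mean_ab + backsolve(U, stats::rnorm(2))
      alpha <- ab[1]; beta <- ab[2]
      # sigma | rest: random-walk Metropolis on log sigma
      theta <- log(sigma)
      theta_new <- theta + stats::rnorm(1, 0, step)
      lr <- log_post_sigma(exp(theta_new), alpha, beta, xi) + theta_new -
        (log_post_sigma(sigma, alpha, beta, xi) + theta)
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        sigma <- exp(theta_new)
        if (s > warmup) acc <- acc + 1L else warm_acc <- warm_acc + 1L
      }
      # adapt the proposal scale toward ~0.44 acceptance during warm-up
      if (s <= warmup && s %% 50 == 0) {
        step <- step * exp(warm_acc / 50 - 0.44)
        warm_acc <- 0L
      }
      if (s > warmup) draws[s - warmup, ] <- c(alpha, beta, sigma)
    }
    list(draws = draws, accept = acc / iter)
  }

  chain_seeds <- vapply(seq_len(chains),
                        function(k) derive_seed(seed, paste0("eiv-chain-", k)),
                        integer(1))
  res <- lapply(chain_seeds, run_chain)
  draws_by_chain <- lapply(res, `[[`, "draws")
  draws <- do.call(rbind, draws_by_chain)

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- unname(stats::quantile(draws[, "beta"], probs))
  diag_of <- function(par) {
    m <- sapply(draws_by_chain, function(d) d[, par])
    c(rhat = split_rhat(m), ess = ess_acf(m))
  }
  dg <- rbind(alpha = diag_of("alpha"), beta = diag_of("beta"), sigma = diag_of("sigma"))
  out <- list(
    intercept = mean(draws[, "alpha"]),
    slope = mean(draws[, "beta"]),
    sigma = mean(draws[, "sigma"]),
    ci = ci,
    level = level,
    significant = ci[1] > 0 || ci[2] < 0,
    n = n,
    draws = draws,
    diagnostics = list(rhat = dg[, "rhat"], ess = dg[, "ess"],
                       accept = mean(vapply(res, `[[`, numeric(1), "accept"))),
    data = list(y = y, y_se = y_se, x = x, x_se = x_se),
    chains = chains, iter = iter, warmup = warmup, seed = seed
  )
  class(out) <- "eiv_fit"
  if (dg["beta", "ess"] < 100 || max(dg[, "rhat"]) > 1.1) {
    warning("slope chain mixing is poor (ESS < 100 or split-Rhat > 1.1); ",
            "consider more iterations", call. = FALSE)
  }
  out
}

# Split-chain potential scale reduction factor (each chain halved).
split_rhat <- function(m) {
  n <- nrow(m)
  half <- floor(n / 2)
  sub <- cbind(m[seq_len(half), , drop = FALSE],
               m[(n - half + 1):n, , drop = FALSE])
  k <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size from pooled-chain autocorrelations (initial
# positive sequence truncation), summed over chains.
ess_acf <- function(m) {
  per_chain <- apply(m, 2, function(v) {
    n <- length(v)
    a <- stats::acf(v, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
    pos <- which(a < 0.05)
    if (length(pos)) a <- a[seq_len(pos[1] - 1)]
    n / (1 + 2 * sum(a))
  })
  sum(per_chain)
}

#' @export
print.eiv_fit <- function(x, ...) {
  cat("Bayesian errors-in-variables regression\n")
  cat(sprintf("  n = %d, %d chains x %d draws (warmup %d)\n",
              x$n, x$chains, x$iter, x$warmup))
  cat(sprintf("  slope: %.4f  %d%% CI [%.4f, %.4f]  %s\n",
              x$slope, round(100 * x$level), x$ci[1], x$ci[2],
              if (x$significant) "(excludes 0)" else "(includes 0)"))
  cat(sprintf("  intercept: %.4f   residual sigma: %.4f\n", x$intercept, x$sigma))
  cat(sprintf("  max split-Rhat: %.3f   min ESS: %.0f\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' @export
coef.eiv_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.eiv_fit <- function(object, ...) {
  data.frame(intercept = object$intercept, slope = object$slope,
             ci_lower = object$ci[1], ci_upper = object$ci[2],
             sigma = object$sigma, significant = object$significant,
             n = object$n, max_rhat = max(object$diagnostics$rhat),
             min_ess = min(object$diagnostics$ess), row.names = NULL)
}

#' @export
confint.eiv_fit <- function(object, parm = "slope", level = NULL, ...) {
  if (!is.null(level) && level != object$level) {
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    return(unname(stats::quantile(object$draws[, "beta"], probs)))
  }
  object$ci
}

#' @export
plot.eiv_fit <- function(x, ...) {
  d <- x$data
  plot(d$x, d$y, pch = 16, col = grDevices::grey(0.4),
       xlab = "x (observed)", ylab = "y (observed)", ...)
  graphics::segments(d$x - d$x_se, d$y, d$x + d$x_se, d$y, col = grDevices::grey(0.8))
  graphics::segments(d$x, d$y - d$y_se, d$x, d$y + d$y_se, col = grDevices::grey(0.8))
  graphics::abline(x$intercept, x$slope, lwd = 2)
  invisible(x)
}

#' Internal-vs-international interrelation analysis by group
#'
#' For each group (continent or alternative label) and direction (in/out),
#' fits the errors-in-variables regression of internal trend slopes on
#' international trend slopes and computes quadrant fractions of the
#' (international, internal) slope scatter. Groups with fewer than
#' \code{min_regions} regions carrying both slopes are skipped.
#'
#' @param trends Output of \code{\link{region_trends}}.
#' @param registry Region registry.
#' @param grouping \code{"continent"} or \code{"group_label"}.
#' @param min_regions Minimum regions per group-direction fit, default 5.
#' @param seed Integer seed for the MCMC.
#' @param ... Passed to \code{\link{fit_eiv}} (chains, iter, warmup).
#' @return list with \code{eiv} (one summary row per group-direction),
#'   \code{quadrants} (quadrant fractions per group-direction) and
#'   \code{fits} (the underlying \code{eiv_fit} objects).
#' @export
interrelate <- function(trends, registry, grouping = c("continent", "group_label"),
                        min_regions = 5L, seed = 1L, ...) {
  grouping <- match.arg(grouping)
  col <- if (grouping == "continent") "continent_id" else "group_label"
  lk <- registry_lookup(registry, col)
  eiv_rows <- list(); quad_rows <- list(); fits <- list()
  for (direction in c("in", "out")) {
    tt <- trends[trends$direction == direction, , drop = FALSE]
    internal <- tt[tt$scope == "internal", c("region_id", "slope", "se")]
    international <- tt[tt$scope == "international", c("region_id", "slope", "se")]
    m <- merge(internal, international, by = "region_id",
               suffixes = c("_internal", "_international"))
    m$group_id <- unname(lk[m$region_id])
    for (g in sort(unique(m$group_id))) {
      mg <- m[m$group_id == g, , drop = FALSE]
      q <- quadrant_fractions(mg$slope_international, mg$slope_internal)
      quad_rows[[length(quad_rows) + 1L]] <- data.frame(
        group_id = g, direction = direction, t(q), n_regions = nrow(mg),
        stringsAsFactors = FALSE)
      if (nrow(mg) < min_regions) next
      fit <- fit_eiv(mg$slope_internal, mg$se_internal,
                     mg$slope_international, mg$se_international,
                     seed = derive_seed(seed, paste0("eiv-", g, "-", direction)), ...)
      fits[[paste(g, direction, sep = "-")]] <- fit
      eiv_rows[[length(eiv_rows) + 1L]] <- cbind(
        data.frame(group_id = g, direction = direction, stringsAsFactors = FALSE),
        summary(fit))
    }
  }
  list(
    eiv = if (length(eiv_rows)) do.call(rbind, eiv_rows) else NULL,
    quadrants = if (length(quad_rows)) do.call(rbind, quad_rows) else NULL,
    fits = fits
  )
}
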