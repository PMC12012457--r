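test_that("flow tabulation does the forced bookkeeping", {
  reg <- toy_registry()
  res <- data.frame(author_id = c("a", "b", "a", "b"),
                    year = c(2004, 2004, 2005, 2005),
                    region_id = c("CA-ON", "CA-BC", "CA-BC", "CA-BC"),
                    country_id = "CA", stringsAsFactors = FALSE)
  no_events <- res[0, ]
  ev0 <- data.frame(author_id = character(0), year = integer(0),
                    origin_region = character(0), origin_country = character(0),
                    dest_region = character(0), dest_country = character(0),
                    scope = character(0))
  fl0 <- tabulate_flows(res, ev0, reg)
  expect_true(all(fl0$I_total == 0) && all(fl0$E_total == 0))
  expect_equal(fl0$N[fl0$region_id == "CA-BC" & fl0$year == 2005], 2)

  ev <- data.frame(author_id = "a", year = 2005,
                   origin_region = "CA-ON", origin_country = "CA",
                   dest_region = "CA-BC", dest_country = "CA",
                   scope = "internal", stringsAsFactors = FALSE)
  fl <- tabulate_flows(res, ev, reg)
  expect_equal(fl$E_internal[fl$region_id == "CA-ON" & fl$year == 2005], 1)
  expect_equal(fl$I_internal[fl$region_id == "CA-BC" & fl$year == 2005], 1)
  expect_equal(sum(fl$I_internal) + sum(fl$I_international), 1)
  expect_equal(sum(fl$E_internal) + sum(fl$E_international), 1)

  bad <- ev; bad$dest_region <- "XX"
  expect_error(tabulate_flows(res, bad, reg), "unknown region")
})

test_that("flows conserve events globally per year-scope and internally per country", {
  w <- default_test_cohort(n_authors = 400, seed = 29)
  inf <- infer_residences(w$cohort$records, w$registry, seed = 29)
  fl <- tabulate_flows(inf$residences, inf$events, w$registry)
  for (sc in c("internal", "international", "total")) {
    icol <- paste0("I_", sc); ecol <- paste0("E_", sc)
    i_by_year <- tapply(fl[[icol]], fl$year, sum)
    e_by_year <- tapply(fl[[ecol]], fl$year, sum)
    expect_equal(i_by_year, e_by_year)
  }
  ev_by_year <- table(inf$events$year)
  tot <- tapply(fl$I_total, fl$year, sum)
  expect_equal(as.vector(tot[names(ev_by_year)]), as.vector(ev_by_year))
  # internal flows balance within each country
  cl <- setNames(w$registry$country_id, w$registry$region_id)
  fl$country <- unname(cl[fl$region_id])
  expect_equal(tapply(fl$I_internal, fl$country, sum),
               tapply(fl$E_internal, fl$country, sum))
})

test_that("annual NMR follows the rate definition and flags empty denominators", {
  reg <- toy_registry()
  fl <- data.frame(region_id = rep("CA-ON", 4), year = 2001:2004,
                   N = c(1000, 1000, 10, 0),
                   I_internal = c(30, 500, 10, 0), I_international = 0,
                   E_internal = c(10, 500, 0, 0), E_international = 0)
  fl$I_total <- fl$I_internal + fl$I_international
  fl$E_total <- fl$E_internal + fl$E_international
  fl$defined <- fl$N > 0
  nmr <- annual_nmr(fl, "internal")
  expect_equal(nmr$nmr_per_1000[1], 20)      # 1000*(30-10)/1000
  expect_equal(nmr$nmr_per_1000[2], 0)       # I = E
  expect_equal(nmr$nmr_per_1000[3], 1000)    # I = N, E = 0
  expect_true(is.na(nmr$nmr_per_1000[4]))    # N = 0 flagged, not dropped
  expect_false(nmr$defined[4])
  # antisymmetry under exchanging inflows and outflows
  sw <- fl; sw$I_internal <- fl$E_internal; sw$E_internal <- fl$I_internal
  expect_equal(annual_nmr(sw, "internal")$nmr_per_1000[1:3],
               -nmr$nmr_per_1000[1:3])
})

test_that("period NMR pools person-years and reduces to the annual rate", {
  reg <- toy_registry()
  fl <- expand.grid(region_id = reg$region_id, year = 2012:2017,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fl$N <- 200
  fl$I_internal <- 6; fl$I_international <- 0
  fl$E_internal <- 2; fl$E_international <- 0
  fl$I_total <- 6; fl$E_total <- 2
  fl$defined <- TRUE
  # constant flows: the six-year rate equals the single-year rate
  p <- period_nmr(fl, 2012:2017, "internal")
  a <- annual_nmr(fl, "internal")
  expect_equal(p$nmr_per_1000, rep(1000 * 4 / 200, 4))
  expect_equal(unique(a$nmr_per_1000), 1000 * 4 / 200)
  # one-year period is exactly the annual value
  p1 <- period_nmr(fl[fl$year == 2013, ], 2013, "internal")
  expect_equal(p1$nmr_per_1000, a$nmr_per_1000[a$period_start == 2013])
})

test_that("period NMR matches a brute-force tally on a simulated cohort", {
  w <- default_test_cohort(n_authors = 400, seed = 37)
  inf <- infer_residences(w$cohort$records, w$registry, seed = 37)
  cw <- censor_window(inf$events, inf$residences)
  fl <- tabulate_flows(cw$residences, cw$events, w$registry)
  p <- period_nmr(fl, 2012:2017, "total")
  ev <- cw$events[cw$events$year %in% 2012:2017, ]
  res <- cw$residences[cw$residences$year %in% 2012:2017, ]
  for (r in p$region_id[p$defined]) {
    I <- sum(ev$dest_region == r)
    E <- sum(ev$origin_region == r)
    N <- sum(res$region_id == r)
    expect_equal(p$nmr_per_1000[p$region_id == r], 1000 * (I - E) / N)
  }
})

test_that("annual rates are count/N and invert exactly", {
  w <- default_test_cohort(n_authors = 300, seed = 41)
  inf <- infer_residences(w$cohort$records, w$registry, seed = 41)
  fl <- tabulate_flows(inf$residences, inf$events, w$registry)
  r <- annual_rates(fl, "in", "internal")
  expect_equal(r$rate[r$defined] * r$N[r$defined], r$count[r$defined])
  expect_true(all(is.na(r$rate[!r$defined])))
  zero <- r[r$count == 0 & r$defined, ]
  expect_true(all(zero$rate == 0))
  # six stacked series carry consistent labels
  ar <- all_rates(fl)
  expect_setequal(unique(ar$migration_type),
                  c("internal-in", "internal-out", "international-in",
                    "international-out", "total-in", "total-out"))
})
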