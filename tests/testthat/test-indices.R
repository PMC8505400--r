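test_that("relative weights normalise the assigned weights", {
  rw <- relative_weights(std_default)
  expect_equal(sum(rw), 1)
  expect_equal(rw[["do"]], 2.85 / 16.95)
  expect_equal(rw[["ph"]], 1 / 16.95)

  # equal weights degenerate to 1/n
  std <- std_default
  std$mwqi_set <- c("tds", "mg", "ca", "cl")
  std$parameters$assigned_weight[
    std$parameters$code %in% std$mwqi_set] <- 1
  expect_equal(unname(relative_weights(std)), rep(0.25, 4))

  std$mwqi_set <- character(0)
  expect_error(relative_weights(std), "empty")
})

test_that("quality ratings scale concentration to the standard", {
  expect_equal(quality_rating("tds", 740.65, std_default), 148.13)
  # at the limit every ordinary parameter rates 100
  for (code in c("tds", "turbidity", "ec", "mg", "ca", "cl", "so4", "no3",
                 "bod")) {
    s <- std_default$parameters$permissible_limit[
      std_default$parameters$code == code]
    expect_equal(quality_rating(code, s, std_default), 100)
  }
  # ideal-value anchors for DO and pH
  expect_equal(quality_rating("do", 14.6, std_default), 0)
  expect_equal(quality_rating("do", 6, std_default), 100)
  expect_equal(quality_rating("ph", 7, std_default), 0)
  expect_equal(quality_rating("ph", 8.5, std_default), 100)

  std <- std_default
  std$parameters$ideal_value[std$parameters$code == "do"] <- 6
  expect_error(quality_rating("do", 5, std), "degenerate")
  expect_error(quality_rating("xx", 1, std_default), "unknown")
})

test_that("MWQI anchors, components and completeness contract hold", {
  std <- std_default
  v <- stats::setNames(
    std$parameters$permissible_limit[match(std$mwqi_set,
                                           std$parameters$code)],
    std$mwqi_set)
  res <- mwqi(v, std)  # everything exactly at standard: ph 8.5, do 6
  expect_equal(res$value, 100)
  expect_equal(res$class_label, "good")

  v0 <- v * 0
  v0[["ph"]] <- 7; v0[["do"]] <- 14.6
  expect_equal(mwqi(v0, std)$value, 0)

  pre <- phase_means("pre_lockdown")
  res <- mwqi(pre, std)
  expect_equal(sum(res$components), res$value)
  expect_length(res$components, 11)

  expect_error(mwqi(pre[setdiff(names(pre), "bod")], std), "bod")
})

test_that("MWQI classes follow the drinking-water scheme boundaries", {
  expect_equal(classify_mwqi(310.37), "unfit for drinking")
  expect_equal(classify_mwqi(101.33), "poor")
  expect_equal(classify_mwqi(c(50, 50.01, 100, 200, 300, 300.01)),
               c("excellent", "good", "good", "poor", "very poor",
                 "unfit for drinking"))
  expect_error(classify_mwqi(NaN), "classification")
})

test_that("HPI is a limit-weighted mean of metal sub-indices", {
  std <- std_default
  # every metal at its limit -> every sub-index 100
  v <- stats::setNames(
    std$parameters$permissible_limit[match(std$hpi_set,
                                           std$parameters$code)],
    std$hpi_set)
  expect_equal(hpi(v, std)$value, 100)

  # one-metal average
  std1 <- std_default
  std1$hpi_set <- "cd"
  expect_equal(hpi(c(cd = 5), std1)$value, 50)

  # unit invariance: scaling concentrations and limits together is a no-op
  set.seed(4)
  m <- random_values()
  h1 <- hpi(m, std)$value
  std_scaled <- std
  std_scaled$parameters$permissible_limit <-
    std_scaled$parameters$permissible_limit * 1000
  h2 <- hpi(m * 1000, std_scaled)$value
  expect_equal(h1, h2)

  expect_error(hpi(m[setdiff(names(m), "fe")], std), "fe")
})

test_that("HMI classes follow the published scheme", {
  expect_equal(classify_hmi(86.06), "very poor")
  expect_equal(classify_hmi(140.01), "unfit for drinking")
  expect_equal(classify_hmi(c(0, 25, 25.01, 50, 75, 100, 100.01)),
               c("excellent", "excellent", "good", "good", "poor",
                 "very poor", "unfit for drinking"))
  expect_error(classify_hmi(-1), "negative")
})

test_that("ecological risk decomposes into contamination and risk factors", {
  std <- std_default
  res <- ecological_risk(c(cd = 10.20, pb = 26.18, cr = 87.67,
                           zn = 39845.45), std)
  expect_equal(res$value, 537.5065, tolerance = 1e-6)
  expect_equal(sum(res$components), res$value)
  expect_equal(res$breakdown$contamination_factor,
               res$breakdown$concentration / res$breakdown$reference_value)
  expect_equal(res$breakdown$risk_factor,
               res$breakdown$toxic_response *
                 res$breakdown$contamination_factor)
  expect_equal(res$degree_of_contamination,
               sum(res$breakdown$contamination_factor))

  # all metals at their preindustrial reference: Cf = 1, RI = sum(Tr) = 38
  at_ref <- ecological_risk(c(cd = 1, pb = 70, cr = 90, zn = 175), std)
  expect_equal(at_ref$value, 38)
  expect_equal(unname(at_ref$breakdown$contamination_factor), rep(1, 4))

  # cadmium alone dominates through its toxic response of 30
  solo <- ecological_risk(c(cd = 10.20, pb = 0, cr = 0, zn = 0), std)
  expect_equal(solo$components[["cd"]], 306.0)
  expect_equal(solo$value, 306.0)

  expect_error(ecological_risk(c(cd = 1, pb = 1, cr = 1), std), "zn")
})

test_that("RI classes honour the strict lower anchors", {
  expect_equal(classify_ri(537.45), "Heavily contaminated")
  expect_equal(classify_ri(124.53), "Practically uncontaminated")
  expect_equal(classify_ri(c(0, 149.99, 150, 300, 600)),
               c("Practically uncontaminated", "Practically uncontaminated",
                 "Moderately contaminated", "Heavily contaminated",
                 "Extremely contaminated"))
  expect_error(classify_ri(-5), "negative")
})

test_that("Carlson TSI averages the three log transforms", {
  res <- tsi(1, 1, 1)
  expect_equal(unname(res$components), c(60.0, 4.15, 30.6))
  expect_equal(res$value, mean(c(60.0, 4.15, 30.6)))

  expect_equal(tsi(2.24, 62.45, 76.09)$value, 61.74745, tolerance = 1e-6)
  expect_equal(tsi(2.79, 18.36, 29.18)$value, 51.67444, tolerance = 1e-6)

  expect_error(tsi(0, 1, 1), "positive")
  expect_error(tsi(1, -2, 1), "positive")
})

test_that("TSI classes span the seven trophic states", {
  expect_equal(classify_tsi(61.99), "medium eutrophic")
  expect_equal(classify_tsi(44.89), "mesotrophic")
  expect_equal(classify_tsi(29.99), "low oligotrophic")
  expect_equal(classify_tsi(c(30, 40, 50, 60, 70, 80, 95)),
               c("high oligotrophic", "mesotrophic", "low eutrophic",
                 "medium eutrophic", "high eutrophic", "very high eutrophic",
                 "very high eutrophic"))
})

test_that("each index matches an independent brute-force oracle on random input", {
  std <- std_default
  p <- std$parameters
  set.seed(101)
  for (i in seq_len(1000)) {
    v <- random_values()

    # MWQI oracle: naive loop over the 11 parameters
    acc <- 0; wsum <- 0
    for (code in c("ph", "tds", "turbidity", "ec", "mg", "ca", "cl", "so4",
                   "no3", "bod", "do")) {
      aw <- p$assigned_weight[p$code == code]
      s <- p$permissible_limit[p$code == code]
      q <- if (code == "ph") (v[[code]] - 7) / (8.5 - 7) * 100
        else if (code == "do") (v[[code]] - 14.6) / (6 - 14.6) * 100
        else v[[code]] / s * 100
      acc <- acc + aw * q
      wsum <- wsum + aw
    }
    expect_equal(mwqi(v, std)$value, acc / wsum, tolerance = 1e-9)

    # HPI oracle
    num <- 0; den <- 0
    for (code in c("zn", "cd", "pb", "ni", "cr", "fe")) {
      s <- p$permissible_limit[p$code == code]
      num <- num + (1 / s) * (v[[code]] / s * 100)
      den <- den + 1 / s
    }
    expect_equal(hpi(v, std)$value, num / den, tolerance = 1e-9)

    # RI oracle
    ri <- 30 * v[["cd"]] / 1 + 5 * v[["pb"]] / 70 + 2 * v[["cr"]] / 90 +
      1 * v[["zn"]] / 175
    expect_equal(ecological_risk(v, std)$value, ri, tolerance = 1e-9)

    # TSI oracle
    ts <- ((60 - 14.41 * log(v[["sd"]])) + (14.42 * log(v[["tp"]]) + 4.15) +
             (30.6 + 9.81 * log(v[["chla"]]))) / 3
    expect_equal(tsi(v[["sd"]], v[["tp"]], v[["chla"]])$value, ts,
                 tolerance = 1e-9)
  }
})

test_that("RI rises with each metal; TSI falls with transparency, rises with nutrients", {
  std <- std_default
  base <- c(cd = 2, pb = 20, cr = 30, zn = 500)
  r0 <- ecological_risk(base, std)$value
  for (code in names(base)) {
    up <- base; up[[code]] <- up[[code]] * 1.5
    expect_gt(ecological_risk(up, std)$value, r0)
  }
  t0 <- tsi(2, 30, 40)$value
  expect_lt(tsi(3, 30, 40)$value, t0)
  expect_gt(tsi(2, 45, 40)$value, t0)
  expect_gt(tsi(2, 30, 60)$value, t0)
})

test_that("classification schemes partition their domain without gaps or overlaps", {
  set.seed(77)
  eps <- 1e-9
  probes <- function(bounds) {
    sort(c(stats::runif(200, 0, 1000), bounds, bounds - eps, bounds + eps))
  }
  for (cl in list(list(fn = classify_mwqi, bounds = c(50, 100, 200, 300)),
                  list(fn = classify_hmi, bounds = c(25, 50, 75, 100)),
                  list(fn = classify_ri, bounds = c(150, 300, 600)),
                  list(fn = classify_tsi,
                       bounds = c(30, 40, 50, 60, 70, 80)))) {
    lab <- cl$fn(probes(cl$bounds))
    expect_false(anyNA(lab))       # no gaps
    expect_length(cl$fn(1), 1)     # scalar in, one label out (no overlap)
    # labels are non-decreasing along the value axis: each class is one
    # contiguous interval
    expect_true(all(diff(match(lab, unique(lab))) >= 0))
  }
})

test_that("index of the mean vector equals the mean of per-sample indices", {
  std <- std_default
  s <- generate_samples(n_sites = 11, seed = 321)
  idx <- compute_indices(s, std)
  for (ph in unique(s$phase)) {
    mv <- colMeans(s[s$phase == ph, setdiff(names(s), c("site_id", "phase"))])
    pick <- function(ix) idx$value[idx$index == ix & idx$phase == ph]
    expect_equal(mean(pick("MWQI")), mwqi(mv, std)$value)
    expect_equal(mean(pick("HPI")), hpi(mv, std)$value)
    expect_equal(mean(pick("RI")), ecological_risk(mv, std)$value)
  }
})

test_that("compute_indices records skipped indices instead of renormalising", {
  std <- std_default
  s <- tiny_samples()
  s$chla <- NULL
  idx <- compute_indices(s, std)
  expect_true(all(is.na(idx$value[idx$index == "TSI"])))
  expect_false(anyNA(idx$value[idx$index != "TSI"]))
  expect_true(any(grepl("chla", attr(idx, "log"))))
})
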