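study_fixture <- function(seed = 1, r = 0, n_regions = 6) {
  cfg <- cfos_sim_config(
    n_regions = n_regions,
    activated_regions_dem = seq_len(n_regions),
    activated_regions_obs = seq_len(n_regions),
    effect_log_fold = 1,
    dyad_coupling_r = r,
    coupled_regions = if (r > 0) seq_len(n_regions) else integer(0),
    seed = seed
  )
  simulate_cfos_study(cfg)
}

test_that("pairings are validated", {
  expect_error(dyad_pairing(c("o1", "o1"), c("d1", "d2")), "exactly one")
  expect_error(dyad_pairing(c("o1", "d1"), c("d1", "d2")), "disjoint")
  p <- dyad_pairing(c("o1", "o2"), c("d1", "d2"))
  expect_equal(nrow(p), 2)
})

test_that("shared-region selection keeps regions increased in both screens", {
  mk_screen <- function(regions, sig, dir) {
    structure(
      data.frame(region = regions, median_a = 1, median_b = 0, U = 9,
                 p = ifelse(sig, 0.01, 0.5), significant = sig,
                 direction = dir),
      class = c("activation_screen", "data.frame")
    )
  }
  a <- mk_screen(c("A", "B", "C", "D"), c(TRUE, TRUE, TRUE, FALSE),
                 c("up", "up", "up", "up"))
  b <- mk_screen(c("A", "B", "C", "D"), c(FALSE, TRUE, TRUE, TRUE),
                 c("up", "up", "down", "up"))
  expect_equal(select_shared_regions(a, b), "B")  # C is down in screen b
  none <- mk_screen(c("A", "B", "C", "D"), rep(FALSE, 4), rep("up", 4))
  expect_equal(select_shared_regions(a, none), character(0))
  expect_error(select_shared_regions(a, mk_screen("A", TRUE, "up")),
               "universe")
  # an empty selection aborts the downstream analysis with a clear message
  tab <- study_fixture()
  pr <- attr(tab, "truth")$pairing
  expect_error(dyad_correlation(tab, pr, character(0)), "aborted")
})

test_that("dyad correlation hits the closed-form extremes", {
  tab <- study_fixture(seed = 2)
  pr <- attr(tab, "truth")$pairing
  regions <- sort(unique(tab$region_acronym))
  # force DEM densities equal to OBS densities within each dyad
  for (i in seq_len(nrow(pr))) {
    o <- tab$animal_id == pr$obs[i]
    d <- tab$animal_id == pr$dem[i]
    tab$density[d] <- tab$density[o]
  }
  expect_equal(unname(dyad_correlation(tab, pr, regions)), rep(1, 6))
  # anti-aligned pairs give r = -1
  for (i in seq_len(nrow(pr))) {
    d <- tab$animal_id == pr$dem[i]
    tab$density[d] <- -tab$density[tab$animal_id == pr$obs[i]]
  }
  expect_equal(unname(dyad_correlation(tab, pr, regions)), rep(-1, 6))
  expect_error(dyad_correlation(tab, pr[1:2, ], regions), ">= 3")
})

test_that("observed r is invariant to per-region affine transforms of both sides", {
  tab <- study_fixture(seed = 3, r = 0.5)
  pr <- attr(tab, "truth")$pairing
  regions <- sort(unique(tab$region_acronym))
  r0 <- dyad_correlation(tab, pr, regions)
  tab2 <- tab
  for (i in seq_along(regions)) {
    sel <- tab2$region_acronym == regions[i]
    tab2$density[sel] <- tab2$density[sel] * (i + 1) + 10 * i
  }
  expect_equal(dyad_correlation(tab2, pr, regions), r0, tolerance = 1e-12)
})

test_that("derangement surrogates never retain a true pair; shuffles avoid only the identity", {
  tab <- study_fixture(seed = 4)
  pr <- attr(tab, "truth")$pairing
  regions <- sort(unique(tab$region_acronym))
  sd7 <- surrogate_null(tab, pr, regions, n_shuffles = 42, seed = 9,
                        method = "derangement")
  perms <- attr(sd7, "permutations")
  expect_length(perms, 42)
  expect_true(all(vapply(perms, function(p) all(p != seq_len(7)), logical(1))))
  expect_equal(length(unique(vapply(perms, paste, character(1), collapse = ","))), 42)
  sh <- surrogate_null(tab, pr, regions, n_shuffles = 42, seed = 9)
  pe <- attr(sh, "permutations")
  expect_true(all(vapply(pe, function(p) any(p != seq_len(7)), logical(1))))
  # seed determinism
  sh2 <- surrogate_null(tab, pr, regions, n_shuffles = 42, seed = 9)
  expect_identical(unclass(sh)[, ], unclass(sh2)[, ])
})

test_that("the derangement count matches inclusion-exclusion (D(7) = 1854 >= 42)", {
  expect_equal(derangement_count(7), 1854)
  # requesting more surrogates than exist is an error
  tab <- study_fixture(seed = 5)
  pr <- attr(tab, "truth")$pairing[1:3, ]
  tab3 <- tab[tab$animal_id %in% c(pr$obs, pr$dem), ]
  expect_equal(derangement_count(3), 2)
  expect_error(
    surrogate_null(tab3, pr, sort(unique(tab3$region_acronym)),
                   n_shuffles = 42, seed = 1, method = "derangement"),
    "1854|derangements|exist"
  )
})

test_that("the 95th-percentile threshold interpolates between order stats 40 and 41", {
  tab <- study_fixture(seed = 6)
  pr <- attr(tab, "truth")$pairing
  regions <- sort(unique(tab$region_acronym))
  obs <- dyad_correlation(tab, pr, regions)
  surr <- surrogate_null(tab, pr, regions, n_shuffles = 42, seed = 2)
  res <- flag_coupled_regions(obs, surr)
  for (i in seq_along(regions)) {
    srt <- sort(surr[i, ])
    expect_gte(res$threshold[i], srt[40])
    expect_lte(res$threshold[i], srt[41])
    expect_equal(res$threshold[i], unname(srt[40] + 0.85 * (srt[41] - srt[40])),
                 tolerance = 1e-12)
  }
})

test_that("flagging is strict, one-sided and positive-direction only", {
  surr <- matrix(seq(-0.9, 0.9, length.out = 42), 2, 42, byrow = TRUE,
                 dimnames = list(c("A", "B"), NULL))
  res <- flag_coupled_regions(c(A = 1, B = -0.2), surr)
  expect_true(res$significant[res$region == "A"])    # above all surrogates
  expect_false(res$significant[res$region == "B"])   # below the median
  # an observation exactly at the threshold is not flagged (strict rule)
  thr <- res$threshold[1]
  res2 <- flag_coupled_regions(c(A = thr, B = 0), surr)
  expect_false(res2$significant[1])
  expect_error(flag_coupled_regions(c(A = 1, B = 0), surr, percentile = 100),
               "percentile")
})

test_that("min-max scaling maps to [0, 1] preserving order, per vector", {
  expect_equal(minmax_scale(c(0, 5, 10)), c(0, 0.5, 1))
  x <- rnorm(20)
  expect_equal(order(minmax_scale(x)), order(x))
  expect_error(minmax_scale(rep(1, 4)), "constant")
  # OBS and DEM sides are scaled independently in the display output
  tab <- study_fixture(seed = 7)
  pr <- attr(tab, "truth")$pairing
  regions <- sort(unique(tab$region_acronym))
  da <- dyad_analysis(tab, pr, regions, seed = 1)
  for (rg in regions) {
    expect_equal(range(da$display[[rg]]$obs), c(0, 1))
    expect_equal(range(da$display[[rg]]$dem), c(0, 1))
  }
})

test_that("full-pipeline region selection recovers planted shared activation", {
  hits <- vapply(1:10, function(i) {
    tab <- simulate_cfos_study(cfos_sim_config(
      n_regions = 20, activated_regions_dem = 1:6, activated_regions_obs = 1:12,
      effect_log_fold = 1.5, coupled_regions = 1:3, dyad_coupling_r = 0.8,
      seed = i + 40
    ))
    tr <- attr(tab, "truth")
    shared <- select_shared_regions(
      differential_activation(tab, "OBS", "CTR"),
      differential_activation(tab, "DEM", "CTR")
    )
    mean(tr$activated_dem %in% shared)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})
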