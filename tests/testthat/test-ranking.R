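fake_results <- function(energies, sites = seq_along(energies)) {
  tibble::tibble(site_atom = sites, dg_atom = 99L,
                 site_class = seq_along(energies), energy_kcal = energies)
}

test_that("threshold windows select the right site sets", {
  p <- rank_sites(fake_results(c(0, 2)), threshold_kcal = 1)
  expect_equal(p$predicted_sites, 1)
  p2 <- rank_sites(fake_results(c(0, 0.5)), threshold_kcal = 1)
  expect_equal(sort(p2$predicted_sites), c(1, 2))
  p3 <- rank_sites(fake_results(c(0.3, 0.1, 5)), threshold_kcal = 0)
  expect_equal(p3$predicted_sites, 2)        # singleton argmin
  expect_true(all(p3$per_complex$relative_energy_kcal >= 0))
})

test_that("exact ties at threshold zero are all reported, ordered by atom", {
  p <- rank_sites(fake_results(c(1.0, 1.0, 3), sites = c(7L, 2L, 5L)),
                  threshold_kcal = 0)
  expect_equal(p$predicted_atoms, c(2L, 7L))
})

test_that("enlarging the threshold never shrinks the predicted set", {
  set.seed(99)
  for (i in 1:20) {
    e <- round(runif(6, 0, 3), 2)
    prev <- integer()
    for (thr in c(0, 0.5, 1, 2, 4)) {
      cur <- rank_sites(fake_results(e), threshold_kcal = thr)$predicted_sites
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("no valid results is a diagnostic failure, not a silent answer", {
  expect_error(rank_sites(fake_results(numeric(0))),
               class = "regiopd_prediction_error")
  expect_error(
    rank_sites(fake_results(NA_real_),
               drop_log = tibble::tibble(site_atom = 1, dg_atom = 2,
                                         reason = "all embeddings failed")),
    "all embeddings failed", class = "regiopd_prediction_error")
})

test_that("evaluation labels follow the three-way definition", {
  p_one <- rank_sites(fake_results(c(0, 2)), threshold_kcal = 1)
  expect_equal(evaluate_prediction(p_one, 1), "correct")
  expect_equal(evaluate_prediction(p_one, 2), "incorrect")
  p_two <- rank_sites(fake_results(c(0, 0.4)), threshold_kcal = 1)
  expect_equal(evaluate_prediction(p_two, 2), "semi_correct")
  expect_error(evaluate_prediction(p_one, 42),
               class = "regiopd_validation_error")
  # exactly one label for every cell of the partition
  for (obs in 1:2) {
    lab <- evaluate_prediction(p_two, obs)
    expect_true(lab %in% c("correct", "semi_correct", "incorrect"))
  }
})

test_that("refinement re-ranks within the threshold window", {
  sub <- sub_phenylpyridine()
  cx_a <- build_complex(sub, list(site_atom = 2, dg_atom = 9))
  cx_b <- build_complex(sub, list(site_atom = 7, dg_atom = 9))
  ens <- generate_conformers(cx_a, seed = 4)
  res <- tibble::tibble(
    site_atom = c(2L, 7L), dg_atom = 9L, site_class = c(1L, 2L),
    energy_kcal = c(0, 0.5),
    complex = list(cx_a, cx_b),
    coords = list(ens$coords[[1]], ens$coords[[2]]))
  p <- rank_sites(res, threshold_kcal = 1)
  expect_equal(length(p$predicted_sites), 2)
  # single-point engine rigged to invert the order decisively
  sp <- engine_spec("mock_sp", energy_map = c(`2` = -100, `7` = -108))
  r <- refine(p, sp)
  expect_true(r$refined)
  expect_equal(r$predicted_sites, 2)         # site 7's class wins after refine
  # refined energies all inside the window keep the membership
  sp2 <- engine_spec("mock_sp", energy_map = c(`2` = -100, `7` = -100.3))
  r2 <- refine(p, sp2)
  expect_setequal(r2$predicted_sites, p$predicted_sites)
  # single predicted site: refine is a no-op
  p_single <- rank_sites(fake_results(c(0, 5)), threshold_kcal = 1)
  expect_identical(refine(p_single, sp), p_single)
})

test_that("null model: closed form, exact interval and simulation agree", {
  nm <- null_model(rep(2, 60), n_sim = 1e5, seed = 2)
  exact <- nm[nm$method == "exact", ]
  sim <- nm[nm$method == "simulation", ]
  expect_equal(exact$expected_correct, 30)
  expect_equal(sim$expected_correct, 30, tolerance = 0.02)
  expect_equal(null_model(4, method = "exact")$expected_correct, 0.25)
  # simulated interval matches the exact Poisson-binomial quantiles
  expect_lte(abs(exact$ci95_lo - sim$ci95_lo), 1)
  expect_lte(abs(exact$ci95_hi - sim$ci95_hi), 1)
  expect_error(null_model(c(2, 1)))
})

test_that("tidy, glance and autoplot provide the broom-style views", {
  p <- rank_sites(fake_results(c(0, 0.4, 3)), threshold_kcal = 1)
  td <- tidy(p)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("site_atom", "relative_energy_kcal",
                    "within_threshold") %in% names(td)))
  g <- glance(p)
  expect_equal(g$n_complexes, 3)
  expect_equal(g$n_predicted_sites, 2)
  expect_s3_class(autoplot(p), "ggplot")
})
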