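test_that("measurement error attenuates trait covariances and inflates diagonals", {
  spec <- model_spec("MR-DoC")
  th <- mid_theta("MR-DoC")
  cov <- expected_covariance(spec, th, "MZ")

  # full reliability is the identity
  expect_equal(add_measurement_error(cov, 1, 1)$sigma, cov$sigma)

  out <- add_measurement_error(cov, 0.9, 0.7)
  # within-person trait covariance scales by sqrt(0.9 * 0.7) = sqrt(0.63)
  expect_equal(out$sigma["T1_1", "T2_1"],
               cov$sigma["T1_1", "T2_1"] * sqrt(0.63))
  expect_equal(out$sigma["T1_1", "T2_2"],
               cov$sigma["T1_1", "T2_2"] * sqrt(0.63))
  # trait diagonal: rel * latent variance + (1 - rel)
  expect_equal(out$sigma["T1_1", "T1_1"],
               0.9 * cov$sigma["T1_1", "T1_1"] + 0.1)
  expect_equal(out$sigma["T2_2", "T2_2"],
               0.7 * cov$sigma["T2_2", "T2_2"] + 0.3)
  # a unit-variance latent trait keeps unit observed variance
  doc <- model_spec("DoC")
  th0 <- parameter_set(g1 = 0)
  cov0 <- add_measurement_error(expected_covariance(doc, th0, "MZ"), 0.9, 0.7)
  expect_equal(unname(diag(cov0$sigma)), rep(1, 4))
  # trait-PGS covariances scale by the trait's sqrt(rel) only
  expect_equal(out$sigma["PS1_1", "T1_1"],
               cov$sigma["PS1_1", "T1_1"] * sqrt(0.9))

  # PGS-only entries are untouched
  ps <- grep("^PS", cov$var_labels)
  expect_equal(out$sigma[ps, ps], cov$sigma[ps, ps])

  # the distortion is not invertible: re-applying with 1/rel cannot undo it
  expect_false(isTRUE(all.equal(
    add_measurement_error(out, 1, 1)$sigma, cov$sigma)))
  expect_error(add_measurement_error(cov, 1.2, 0.7), "rel1")
})

test_that("re injection sets the E covariance for a target correlation", {
  th <- parameter_set(eX2 = 0.5, eY2 = 0.5)
  expect_equal(inject_re(th, 0)$covE, 0)
  expect_equal(inject_re(th, 0.3)$covE, 0.15)
  th2 <- inject_re(mid_theta("DoC"), 0.3)
  expect_equal(unname(component_correlations(th2)["re"]), 0.3)
  expect_error(inject_re(th, 1.2), "re_value")
  # cross-twin E contributions stay zero after injection
  sig <- expected_covariance(model_spec("DoC"),
                             update_parameters(th2, g1 = 0, covA = 0, covC = 0),
                             "MZ")$sigma
  expect_equal(sig["T1_1", "T2_2"], 0)  # no cross-twin E path
  expect_equal(sig["T1_1", "T2_1"], th2$covE)
})

test_that("marginalization extracts the nested model's observed block", {
  spec3 <- model_spec("MR-DoC2")
  th <- mid_theta("MR-DoC2")
  cov <- expected_covariance(spec3, th, "DZ")
  doc <- marginalize(cov, model_spec("DoC"))
  expect_identical(doc$var_labels, c("T1_1", "T2_1", "T1_2", "T2_2"))
  expect_equal(doc$sigma["T1_1", "T2_2"], cov$sigma["T1_1", "T2_2"])
  # marginalizing to the model itself is the identity
  expect_equal(marginalize(cov, spec3)$sigma, cov$sigma)
  expect_error(marginalize(doc, spec3), "absent")
})

test_that("nested fits to marginalized data recover shared parameters", {
  # MR-DoC2 cell with the instrument block disconnected reduces to DoC
  th <- update_parameters(mid_theta("MR-DoC2"),
                          b1 = 0, b3 = 0, rf = 0, g2 = 0, covE = 0)
  spec3 <- model_spec("MR-DoC2")
  doc <- model_spec("DoC")
  S_mz <- marginalize(expected_covariance(spec3, th, "MZ"), doc)
  S_dz <- marginalize(expected_covariance(spec3, th, "DZ"), doc)
  f <- fit_model(doc, S_mz, S_dz, start = th)
  expect_equal(f$estimates$g1, th$g1, tolerance = 1e-5)
  expect_lt(f$minus2lnL, 1e-6)
})

test_that("exact samples reproduce the target moments to machine precision", {
  th <- mid_theta("DoC")
  cov <- expected_covariance(model_spec("DoC"), th, "DZ")
  x <- exact_sample(cov, n = 500, seed = 11)
  expect_equal(dim(x), c(500L, 4L))
  expect_lt(max(abs(colMeans(x))), 1e-12)
  expect_lt(max(abs(cov(x) - cov$sigma)), 1e-10)
  # determinism
  expect_identical(x, exact_sample(cov, n = 500, seed = 11))
  expect_false(identical(x, exact_sample(cov, n = 500, seed = 12)))
  expect_error(exact_sample(cov, n = 4, seed = 1), "exceed")
})

test_that("raw exact samples and covariance input give the same NCP", {
  spec <- model_spec("DoC")
  th <- mid_theta("DoC")
  S_mz <- expected_covariance(spec, th, "MZ")
  S_dz <- expected_covariance(spec, th, "DZ")
  x_mz <- exact_sample(S_mz, n = 1000, seed = 21)
  x_dz <- exact_sample(S_dz, n = 1000, seed = 22)
  r_cov <- ncp_for_test(spec, S_mz, S_dz, start = th,
                        null_constraints = list(g1 = 0))
  r_raw <- ncp_for_test(spec, sample_covariance(x_mz, "MZ"),
                        sample_covariance(x_dz, "DZ"), start = th,
                        null_constraints = list(g1 = 0))
  expect_equal(r_raw$ncp, r_cov$ncp, tolerance = 1e-4)
})

test_that("generating covariances stay positive definite under all distortions", {
  # sweep over random Table-1-style cells crossed with the distortions
  for (model in c("DoC", "MR-DoC", "MR-DoC2")) {
    spec <- model_spec(model)
    for (s in 1:4) {
      th <- random_theta(model, seed = 900 + s)
      for (re in c(NA, 0.3, -0.3)) {
        th2 <- if (is.na(re)) th else inject_re(th, re)
        for (z in c("MZ", "DZ")) {
          cov <- expected_covariance(spec, th2, z)
          for (withme in c(FALSE, TRUE)) {
            sig <- if (withme)
              add_measurement_error(cov, 0.9, 0.7)$sigma else cov$sigma
            ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
            # PSD always; strictly PD except the degenerate MZ PGS copies
            expect_gt(min(ev), -1e-10)
            idx <- twinmr:::.lik_index(spec, z)
            ev2 <- eigen(sig[idx, idx], symmetric = TRUE,
                         only.values = TRUE)$values
            expect_gt(min(ev2), 1e-8)
          }
        }
      }
    }
  }
})
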