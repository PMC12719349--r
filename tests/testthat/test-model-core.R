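test_that("parameter-set construction enforces admissibility", {
  expect_error(parameter_set(g1 = 2, g2 = 0.6), "feedback")
  expect_error(parameter_set(rel1 = 0), "rel1")
  expect_error(parameter_set(rel2 = 1.2), "rel2")
  expect_error(parameter_set(rf = 1.5), "rf")
  expect_error(update_parameters(mid_theta("DoC"), nonsense = 1), "unknown")
  th <- update_parameters(mid_theta("DoC"), g1 = 0.1)
  expect_equal(th$g1, 0.1)
})

test_that("component correlations derive from covariances and invert exactly", {
  th <- parameter_set(aX2 = 0.4, aY2 = 0.3, covA = 0)
  expect_equal(unname(component_correlations(th)["ra"]), 0)

  th2 <- correlations_to_covariances(th, ra = 0.2)
  expect_equal(th2$covA, 0.2 * sqrt(0.12))

  # round-trip through the Table-level correlations is exact
  for (r in c(0.1, 0.2, 0.3)) {
    th3 <- correlations_to_covariances(
      parameter_set(aX2 = 0.5, aY2 = 0.3, cX2 = 0.2, cY2 = 0.1,
                    eX2 = 0.3, eY2 = 0.6), ra = r, rc = r, re = r)
    expect_equal(unname(component_correlations(th3)), rep(r, 3))
  }

  # undefined correlations are NA, never NaN
  th4 <- parameter_set(aX2 = 0, covA = 0)
  expect_true(is.na(component_correlations(th4)["ra"]))
})

test_that("covariances with no connecting paths follow the classical twin rules", {
  spec <- model_spec("DoC")
  th <- parameter_set(g1 = 0, aX2 = 0.4, cX2 = 0.2, eX2 = 0.4,
                      covA = 0, covC = 0)
  mz <- expected_covariance(spec, th, "MZ")
  dz <- expected_covariance(spec, th, "DZ")
  # no path connects the traits: all T1-T2 covariances vanish
  expect_equal(mz$sigma["T1_1", "T2_1"], 0)
  expect_equal(mz$sigma["T1_1", "T2_2"], 0)
  # cross-twin trait covariance: a + c for MZ, a/2 + c for DZ
  expect_equal(mz$sigma["T1_1", "T1_2"], 0.6)
  expect_equal(dz$sigma["T1_1", "T1_2"], 0.4)
})

test_that("without C and cross paths every DZ cross-twin entry is half the MZ entry", {
  for (model in c("DoC", "MR-DoC", "MR-DoC2")) {
    spec <- model_spec(model)
    th <- update_parameters(mid_theta(model),
                            g1 = 0, g2 = 0, b1 = 0, b2 = 0, b3 = 0,
                            cX2 = 0, cY2 = 0, covC = 0, covE = 0,
                            eX2 = 0.6, eY2 = 0.6)
    k <- length(spec$observed_vars)
    mz <- expected_covariance(spec, th, "MZ")$sigma
    dz <- expected_covariance(spec, th, "DZ")$sigma
    cross_mz <- mz[1:k, k + 1:k]
    cross_dz <- dz[1:k, k + 1:k]
    expect_equal(cross_dz, cross_mz / 2, tolerance = 1e-12)
  }
})

test_that("twin blocks are exchangeable and the matrix is symmetric PSD", {
  for (model in c("DoC", "MR-DoC", "MR-DoC2")) {
    spec <- model_spec(model)
    k <- length(spec$observed_vars)
    for (s in 1:5) {
      th <- random_theta(model, seed = 100 + s)
      for (z in c("MZ", "DZ")) {
        sig <- expected_covariance(spec, th, z)$sigma
        expect_equal(sig, t(sig))
        perm <- c(k + 1:k, 1:k)   # swap twin 1 and twin 2
        expect_equal(unname(sig[perm, perm]), unname(sig))
        expect_true(min(eigen(sig, symmetric = TRUE,
                              only.values = TRUE)$values) > -1e-10)
      }
    }
  }
})

test_that("DoC covariance is nested in the instrumented models' trait blocks", {
  th <- mid_theta("DoC")
  doc <- model_spec("DoC")
  for (z in c("MZ", "DZ")) {
    base <- expected_covariance(doc, th, z)
    # MR-DoC with b1 = b2 = 0
    m1 <- expected_covariance(model_spec("MR-DoC"), th, z)
    expect_equal(marginalize(m1, doc)$sigma, base$sigma)
    # MR-DoC2 with b1 = b3 = rf = 0 (g2 = 0 here as well)
    m2 <- expected_covariance(model_spec("MR-DoC2"), th, z)
    expect_equal(marginalize(m2, doc)$sigma, base$sigma)
  }
})

test_that("fully reliable exogenous traits have unit variance", {
  spec <- model_spec("DoC")
  th <- parameter_set(g1 = 0, aX2 = 0.35, cX2 = 0.25, eX2 = 0.4)
  sig <- expected_covariance(spec, th, "MZ")$sigma
  expect_equal(unname(diag(sig)), rep(1, 4))
})

test_that("expected covariances match the Monte-Carlo structural simulator", {
  # light sweep; the full 20-cell n = 1e6 comparison runs in the
  # acceptance suite
  n <- 200000
  for (model in c("DoC", "MR-DoC", "MR-DoC2")) {
    spec <- model_spec(model)
    for (s in 1:2) {
      th <- random_theta(model, seed = 7 * s + 3)
      for (z in c("MZ", "DZ")) {
        sig <- expected_covariance(spec, th, z)$sigma
        x <- simulate_twin_pairs(th, model, z, n, seed = 1000 + s)
        expect_lt(max_cov_z(sig, x), 5)
      }
    }
  }
})

test_that("reliability enters the model and the covariance operator identically", {
  for (model in c("DoC", "MR-DoC2")) {
    spec <- model_spec(model)
    th <- mid_theta(model)
    th_rel <- update_parameters(th, rel1 = 0.9, rel2 = 0.7)
    for (z in c("MZ", "DZ")) {
      via_theta <- expected_covariance(spec, th_rel, z)
      via_op <- add_measurement_error(expected_covariance(spec, th, z),
                                      0.9, 0.7)
      expect_equal(via_theta$sigma, via_op$sigma, tolerance = 1e-12)
    }
  }
})

test_that("standardize rescales to correlations and is idempotent", {
  spec <- model_spec("MR-DoC2")
  th <- mid_theta("MR-DoC2")
  cov <- expected_covariance(spec, th, "DZ")
  std <- standardize(cov)
  expect_equal(unname(diag(std$sigma)), rep(1, 8))
  expect_equal(standardize(std)$sigma, std$sigma)

  tc <- twin_covariance(diag(c(4, 1, 4, 1)), "MZ", c("T1_1", "T2_1", "T1_2", "T2_2"))
  tc$sigma["T1_1", "T2_1"] <- tc$sigma["T2_1", "T1_1"] <- 1
  expect_equal(standardize(tc)$sigma["T1_1", "T2_1"], 0.5)

  bad <- twin_covariance(diag(c(1, -1, 1, -1)), "MZ",
                         c("T1_1", "T2_1", "T1_2", "T2_2"))
  expect_error(standardize(bad), "diagonal")
})

test_that("rescaled parameters reproduce the standardized covariance exactly", {
  for (model in c("DoC", "MR-DoC2")) {
    spec <- model_spec(model)
    th <- random_theta(model, seed = 42)
    S <- expected_covariance(spec, th, "DZ")
    k <- length(spec$observed_vars)
    d <- 1 / sqrt(diag(S$sigma)[1:k])
    names(d) <- spec$observed_vars
    th2 <- rescale_parameters(th, d)
    expect_equal(expected_covariance(spec, th2, "DZ")$sigma,
                 standardize(S)$sigma, tolerance = 1e-12)
    expect_equal(expected_covariance(spec, th2, "MZ")$sigma,
                 standardize(expected_covariance(spec, th, "MZ"))$sigma,
                 tolerance = 1e-12)
  }
})

test_that("covariance CSV round-trip preserves the matrix", {
  th <- mid_theta("MR-DoC")
  cov <- expected_covariance(model_spec("MR-DoC"), th, "MZ")
  path <- withr::local_tempfile(fileext = ".csv")
  write_twin_covariance(cov, path)
  back <- read_twin_covariance(path, "MZ")
  expect_equal(back$sigma, cov$sigma, tolerance = 1e-12)
})
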