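test_that("similarity is a [0,1] cosine score with the documented geometry", {
  rv <- ratio_vector(random_panel(3))
  expect_equal(similarity(rv, rv), 1)

  # scale invariance in ratio mode: any positive rescaling of the panel
  p <- random_panel(4)
  expect_equal(similarity(ratio_vector(p), ratio_vector(p * 2.7)), 1)

  # orthogonal log-feature vectors land at the affine midpoint (1+cos)/2
  expect_equal(similarity(c(1, 0), c(0, 1)), 0.5)
  # hand-computed 2-D example: cos(45 deg) = 1/sqrt(2)
  expect_equal(similarity(c(1, 0), c(1, 1)), (1 + 1 / sqrt(2)) / 2)

  expect_error(similarity(c(1, 2), c(1, 2, 3)), "dimension mismatch")
  expect_error(similarity(c(1, NA), c(1, 2)), "non-finite")
  expect_error(similarity(ratio_vector(p), percent_vector(p)),
               "different modes")
})

test_that("classification agrees with a brute-force Bayes oracle on tiny dbs", {
  q <- c(1, 0.2, 0.1)
  vecs <- list(c(1.1, 0.25, 0.1), c(0.9, 0.15, 0.12),
               c(-0.5, 1, 0.8), c(-0.4, 1.2, 0.6), c(0.2, -1, 0.5))
  labels <- c("X", "X", "Y", "Y", "Z")
  db <- reference_db(vecs, labels, mode = "ratio")
  cfg <- classifier_config(k = 2)
  res <- classify_profile(q, db, cfg)

  # oracle: explicit enumeration of neighbor similarities (centered on the
  # database mean, as the classifier documents), mean of top-2
  mu <- colMeans(do.call(rbind, vecs))
  sims <- vapply(vecs, function(v) cosine01(v - mu, q - mu), numeric(1))
  lik <- vapply(c("X", "Y", "Z"), function(g) {
    s <- sort(sims[labels == g], decreasing = TRUE)
    mean(s[seq_len(min(2, length(s)))])
  }, numeric(1))
  post <- lik / sum(lik)  # uniform priors and unit corrections cancel
  expect_equal(res$posterior, post, tolerance = 1e-12)
  expect_identical(res$predicted, "X")
  expect_equal(sum(res$posterior), 1)
  expect_equal(res$coefficient, 1 + 99 * max(post))
})

test_that("degenerate databases follow the documented contracts", {
  q <- c(1, 2, 3)
  # single-class db: that class with posterior 1
  db1 <- reference_db(list(c(1, 2, 3.1), c(1, 2.2, 3)), c("PCa", "PCa"),
                      mode = "ratio")
  r1 <- classify_profile(q, db1)
  expect_identical(r1$predicted, "PCa")
  expect_equal(unname(r1$posterior), 1)

  # exactly symmetric classes: posterior (0.5, 0.5), tie to the best neighbor
  db2 <- reference_db(list(c(1, 1, 0), c(0, 1, 1)), c("A", "B"),
                      mode = "ratio")
  r2 <- classify_profile(c(0, 1, 0), db2)
  expect_equal(unname(r2$posterior), c(0.5, 0.5))
  expect_identical(r2$predicted, "A")  # equal sims: first best neighbor

  expect_error(reference_db(list(), character(0)), "empty")
  expect_error(
    classify_profile(q, reference_db(list(c(1, 2, 3)), "PCa", ids = "S1",
                                     mode = "ratio"),
                     query_id = "S1"),
    "identity match")
})

test_that("correction factors converge, stay clipped and update deterministically", {
  st <- posterior_state(c("PCa", "BPH", "HC"), rate = 0.05)
  st$correction[] <- c(1.8, 0.6, 1.2)
  for (i in 1:600) st <- update_correction(st, "PCa", "PCa")
  expect_equal(unname(st$correction), rep(1, 3), tolerance = 1e-6)
  expect_equal(st$step, 600L)

  # 10,000 random outcomes never leave the clip range
  set.seed(99)
  st <- posterior_state(c("PCa", "BPH", "HC"), rate = 0.05, clip = c(0.5, 2))
  classes <- c("PCa", "BPH", "HC")
  for (i in 1:10000) {
    st <- update_correction(st, sample(classes, 1), sample(classes, 1))
    expect_true(all(st$correction >= 0.5 & st$correction <= 2))
  }

  s0 <- posterior_state(classes)
  expect_identical(update_correction(s0, "PCa", "BPH"),
                   update_correction(s0, "PCa", "BPH"))

  # calibration raises the factor of a systematically missed class
  co <- toy_cohort(3, seed = 5)
  vecs <- lapply(seq_len(nrow(co)), function(i)
    ratio_vector(steroid_panel(cohort_panels(co)[i, ])))
  db <- reference_db(vecs, co$class, co$id, mode = "ratio")
  st <- calibrate_corrections(db, classifier_config(), steps = 50)
  expect_equal(st$step, 50L)
  expect_true(all(st$correction >= 0.5 & st$correction <= 2))
})

test_that("leave-one-out classification is deterministic and separates separable classes", {
  co <- toy_cohort(4, seed = 2, jitter_sd = 0.03)
  r1 <- loo_classify(co, "ratio")
  r2 <- loo_classify(co, "ratio")
  expect_identical(r1, r2)

  # tight, distinct classes are recovered perfectly
  expect_equal(mean(r1$predicted == r1$truth), 1)

  # posterior rows normalize; coefficients live on the 1-100 scale
  expect_equal(unname(rowSums(r1[, c("p_BPH", "p_HC", "p_PCa")])),
               rep(1, nrow(r1)))
  expect_true(all(r1$coefficient >= 1 & r1$coefficient <= 100))

  expect_error(loo_classify(co[co$class == "PCa", ], "ratio"),
               "two classes")
})

test_that("mode-specific scale invariances hold and break where expected", {
  co <- toy_cohort(4, seed = 8)
  base_r <- loo_classify(co, "ratio")
  base_a <- loo_classify(co, "absolute")

  # globally rescaling one subject's panel changes nothing in either mode
  co2 <- co
  co2[3, steroid_analytes()] <- co2[3, steroid_analytes()] * 5
  expect_equal(loo_classify(co2, "ratio"), base_r)
  expect_equal(loo_classify(co2, "absolute"), base_a)

  # but scaling a single analyte does change the absolute-percent profile
  co3 <- co
  co3$testosterone[3] <- co3$testosterone[3] * 50
  alt_a <- loo_classify(co3, "absolute")
  expect_false(isTRUE(all.equal(alt_a[3, c("p_BPH", "p_HC", "p_PCa")],
                                base_a[3, c("p_BPH", "p_HC", "p_PCa")])))
})

test_that("coefficient band rule reproduces the reported classification column", {
  expect_identical(band_classify(44.5), "PCa")
  expect_identical(band_classify(22.6), "BPH")
  expect_identical(band_classify(5.3), "HC")

  tab <- builtin_table1()
  expect_identical(band_classify(tab$coefficient), tab$ratio_rule)
})

test_that("rematch averaging of the coefficient is seeded and bounded", {
  co <- toy_cohort(4, seed = 12)
  cfg <- classifier_config(n_rematch = 25, seed = 42)
  r1 <- loo_classify(co, "ratio", cfg)
  r2 <- loo_classify(co, "ratio", cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$coefficient >= 1 & r1$coefficient <= 100))
  expect_error(classifier_config(n_rematch = 5), "seed")
})
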