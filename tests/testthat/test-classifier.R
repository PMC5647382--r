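test_that("both models separate the training cohort and emit calibrated probabilities", {
  fx <- trained_fixture()
  co <- fx$cohort; x <- fx$beta; mods <- fx$models

  full_calls <- classify_cohort(beta_matrix(unclass(x)[, mods$full$loci]),
                                mods$full, probability_threshold = 0)
  sig_calls <- classify_cohort(x, mods$signature, probability_threshold = 0)
  expect_equal(mean(full_calls$call == as.character(co$labels)), 1)
  expect_equal(mean(sig_calls$call == as.character(co$labels)), 1)

  probs <- as.matrix(sig_calls[, mods$signature$classes])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
})

test_that("genome-scale and signature calls are concordant on held-out data", {
  fx <- trained_fixture()
  # a fresh cohort drawn from the same population: same informative-locus
  # structure, new samples
  held <- simulate_cohort(synthetic_config(samples_per_subgroup = 12L,
                                           n_loci = 400L,
                                           informative_per_subgroup = 30L,
                                           seed = 8L),
                          informative_loci = fx$cohort$informative_loci)
  xh <- beta_matrix(impute_locus_median(held$beta))
  full <- classify_cohort(beta_matrix(unclass(xh)[, fx$models$full$loci]),
                          fx$models$full, probability_threshold = 0)
  sig <- classify_cohort(xh, fx$models$signature, probability_threshold = 0)
  expect_gte(mean(full$call == sig$call), 0.95)
})

test_that("training validates its inputs", {
  fx <- trained_fixture()
  co <- fx$cohort; x <- fx$beta
  expect_error(train_models(x, rep("A", nrow(x)), fx$signature),
               "two classes")
  bad_sig <- signature_definition(c(fx$signature$locus_id[-1L], "cg99999"))
  expect_error(train_models(x, co$labels, bad_sig), "absent")
})

test_that("EM imputation is the identity on complete vectors", {
  fx <- trained_fixture()
  v <- setNames(as.numeric(fx$beta[3L, fx$signature$locus_id]),
                fx$signature$locus_id)
  expect_identical(impute_missing_em(v, fx$models$signature), v)
})

test_that("EM imputation matches the Schur-complement conditional mean", {
  fx <- trained_fixture()
  model <- fx$models$signature
  mu <- model$imputation$mean
  sigma <- model$imputation$cov
  p <- length(mu)

  set.seed(50)
  for (trial in 1:5) {
    z <- as.numeric(rmvn(1L, mu, sigma))
    x <- setNames(1 / (1 + 2^(-z)), model$loci)    # inverse logit2
    miss <- sample.int(p, 3L)
    xm <- x; xm[miss] <- NA

    got <- impute_missing_em(xm, model, tol = 1e-14)

    # oracle: Gaussian conditional mean of the missing block via the
    # Schur complement, computed on the logit2 scale
    zc <- log2(pmin(pmax(x, 0.01), 0.99) /
                 (1 - pmin(pmax(x, 0.01), 0.99)))
    obs <- setdiff(seq_len(p), miss)
    cond <- mu[miss] + sigma[miss, obs] %*%
      solve(sigma[obs, obs], zc[obs] - mu[obs])
    expected <- 1 / (1 + 2^(-as.numeric(cond)))
    expect_equal(unname(got[miss]), expected, tolerance = 1e-6)
    # observed coordinates are untouched and imputed ones stay in [0,1]
    expect_identical(got[obs], xm[obs])
    expect_true(all(got[miss] >= 0 & got[miss] <= 1))
  }
})

test_that("more missing loci than tolerated aborts imputation with a QC signal", {
  fx <- trained_fixture()
  v <- setNames(as.numeric(fx$beta[1L, fx$signature$locus_id]),
                fx$signature$locus_id)
  v[1:7] <- NA
  expect_error(impute_missing_em(v, fx$models$signature),
               class = "minsig_locus_qc_fail")
})

test_that("missing-loci calibration returns a sane threshold on a smoke run", {
  fx <- trained_fixture()
  thr <- calibrate_missing_threshold(fx$models$signature, fx$beta,
                                     n_boot = 10L, seed = 2L)
  expect_true(thr >= 0L && thr <= 16L)
  curve <- attr(thr, "agreement")
  expect_identical(nrow(curve), 17L)
  expect_true(all(diff(curve$smoothed) <= 0))
})

test_that("a signature with no redundancy collapses at the first masked locus", {
  # one locus is the sole separator of Grp3 vs Grp4; every other locus is
  # identical between those classes, so masking the critical locus leaves
  # the Grp3/Grp4 decision at chance and agreement collapses at j = 1
  set.seed(51)
  n_per <- 20L
  classes <- c("WNT", "SHH", "Grp3", "Grp4")
  labels <- rep(classes, each = n_per)
  n <- length(labels)
  x <- cbind(
    wnt = ifelse(labels == "WNT", runif(n, 0.9, 1), runif(n, 0, 0.1)),
    shh = ifelse(labels == "SHH", runif(n, 0.9, 1), runif(n, 0, 0.1)),
    g34 = ifelse(labels %in% c("Grp3", "Grp4"),
                 runif(n, 0.9, 1), runif(n, 0, 0.1)),
    crit = ifelse(labels == "Grp3", runif(n, 0.9, 1), runif(n, 0, 0.1)))
  rownames(x) <- sprintf("s%02d", seq_len(n))
  sig <- signature_definition(colnames(x))
  mods <- train_models(beta_matrix(x), labels, sig, n_top = 4L, seed = 52L)
  thr <- calibrate_missing_threshold(mods$signature, beta_matrix(x),
                                     n_boot = 200L, tolerance = 0.99,
                                     seed = 53L)
  expect_identical(as.integer(thr), 0L)
})

test_that("probability-threshold calibration finds the error-free grid point", {
  # perfectly separated predictions: the smallest grid value qualifies
  probs <- cbind(A = c(1, 1, 0), B = c(0, 0, 1))
  expect_identical(calibrate_probability_threshold(probs, c("A", "A", "B")),
                   0)

  # errors confined below 0.7: exhaustive grid search must return 0.70
  set.seed(54)
  maxp <- c(runif(40, 0.71, 1), runif(20, 0.3, 0.699))
  predicted <- rep("A", 60)
  truth <- c(rep("A", 40), sample(c("A", "B"), 20, TRUE, c(0.5, 0.5)))
  truth[41:42] <- "B"                   # guarantee errors below 0.7
  maxp[41:42] <- c(0.695, 0.64)         # an error just under the boundary
  grid_best <- NULL                     # independent exhaustive search
  for (t in seq(0, 1, 0.01)) {
    above <- maxp >= t
    if (any(above) && mean(predicted[above] != truth[above]) == 0) {
      grid_best <- t; break
    }
  }
  got <- calibrate_probability_threshold(maxp, truth, predicted = predicted)
  expect_equal(got, grid_best)
  expect_equal(got, 0.70)

  expect_error(calibrate_probability_threshold(cbind(A = 0.6, B = 0.4),
                                               truth = "B"),
               "tolerance")
})

test_that("models ship with the default thresholds", {
  fx <- trained_fixture()
  expect_identical(fx$models$signature$probability_threshold, 0.69)
  expect_identical(fx$models$signature$max_missing, 6L)
})

test_that("the QC cascade orders its rules and is deterministic", {
  fx <- trained_fixture()
  model <- fx$models$signature
  v <- setNames(as.numeric(fx$beta[2L, model$loci]), model$loci)

  r <- classify_sample(v, model)
  expect_identical(r$qc_code, "PASS")
  expect_identical(r$call, as.character(fx$cohort$labels[2L]))
  expect_identical(r$call,
                   names(r$probabilities)[which.max(r$probabilities)])

  # repeat classification gives byte-identical output (no hidden RNG)
  expect_identical(classify_sample(v, model), r)

  # below-threshold maximum probability gives NC
  r_nc <- classify_sample(v, model, probability_threshold = 1)
  expect_identical(r_nc$call, "NC")
  expect_identical(r_nc$qc_code, "BELOW_THRESHOLD")

  # 7 missing loci fail locus QC before any classification
  v7 <- v; v7[1:7] <- NA
  r7 <- classify_sample(v7, model)
  expect_identical(r7$call, "FAIL")
  expect_identical(r7$qc_code, "LOCUS_QC_FAIL")
  # ... while 6 are tolerated
  v6 <- v; v6[1:6] <- NA
  expect_identical(classify_sample(v6, model)$qc_code, "PASS")

  # conversion failure dominates even a complete, confident sample
  rec <- simulate_assay_record(v, fx$signature, noise_sd = 0,
                               conversion_fail = TRUE, seed = 55L)
  rf <- classify_sample(rec, model)
  expect_identical(rf$call, "FAIL")
  expect_identical(rf$qc_code, "BISULFITE_FAIL")
})

test_that("replicate assay records of one sample agree in their call", {
  fx <- trained_fixture()
  model <- fx$models$signature
  set.seed(56)
  rows <- sample(nrow(fx$beta), 40L, replace = TRUE)
  agree <- vapply(seq_along(rows), function(i) {
    v <- setNames(as.numeric(fx$beta[rows[i], model$loci]), model$loci)
    r1 <- classify_sample(simulate_assay_record(v, fx$signature,
                                                noise_sd = 0.02), model,
                          probability_threshold = 0)
    r2 <- classify_sample(simulate_assay_record(v, fx$signature,
                                                noise_sd = 0.02), model,
                          probability_threshold = 0)
    r1$call == r2$call
  }, TRUE)
  expect_gte(mean(agree), 0.95)
})

test_that("model JSON serialisation restores an equivalent classifier", {
  fx <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fx$models$signature, path)
  back <- read_model_json(path)
  v <- setNames(as.numeric(fx$beta[5L, fx$signature$locus_id]),
                fx$signature$locus_id)
  a <- classify_sample(v, fx$models$signature)
  b <- classify_sample(v, back)
  expect_identical(a$call, b$call)
  expect_equal(a$probabilities, b$probabilities, tolerance = 1e-12)
  expect_identical(back$max_missing, 6L)
  expect_identical(back$probability_threshold, 0.69)
})
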