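test_that("moderated t reduces to the ordinary two-sample t when d0 = 0", {
  co <- small_cohort(seed = 31L, samples = 8L, loci = 60L, informative = 10L)
  x <- complete_beta(co)
  st <- moderated_t_stats(x, co$labels, "WNT", prior_df = 0)
  in_g <- co$labels == "WNT"
  ordinary <- vapply(st$locus_id, function(l)
    unname(t.test(x[in_g, l], x[!in_g, l], var.equal = TRUE)$statistic), 0)
  expect_equal(st$moderated_t, unname(ordinary), tolerance = 1e-10)
})

test_that("complete shrinkage pins every variance to the prior", {
  co <- small_cohort(seed = 32L, samples = 6L, loci = 50L, informative = 10L)
  x <- complete_beta(co)
  st <- moderated_t_stats(x, co$labels, "SHH", prior_df = Inf,
                          prior_var = 0.02)
  expect_true(all(st$moderated_s2 == 0.02))
})

test_that("moderated t matches a brute-force evaluation on a small toy", {
  # loci with strongly heterogeneous variances so the variance-prior
  # moment fit is finite and actually shrinks
  set.seed(33)
  x <- cbind(l1 = 0.2 + rnorm(6, 0, 0.005),
             l2 = 0.5 + rnorm(6, 0, 0.08),
             l3 = 0.7 + rnorm(6, 0, 0.25))
  x <- pmin(pmax(x, 0), 1)
  rownames(x) <- sprintf("s%d", 1:6)
  labels <- rep(c("g", "rest"), each = 3L)
  st <- moderated_t_stats(beta_matrix(x), labels, "g")
  d0 <- st$prior_df[1L]; s02 <- st$prior_var[1L]
  expect_true(is.finite(d0) && d0 > 0)
  brute <- brute_moderated_t(x, labels == "g", d0, s02)
  names(brute) <- colnames(x)
  expect_equal(st$moderated_t, unname(brute[st$locus_id]),
               tolerance = 1e-10)
  # shrunk variance lies between the observed variance and the prior
  expect_true(all(st$moderated_s2 >= pmin(st$ordinary_s2, s02) - 1e-12))
  expect_true(all(st$moderated_s2 <= pmax(st$ordinary_s2, s02) + 1e-12))
  expect_true(all(st$adjusted_p >= st$p_value - 1e-15))
})

test_that("the empirical Bayes fit agrees with limma's squeezeVar", {
  skip_if_not_installed("limma")
  co <- small_cohort(seed = 34L, samples = 10L, loci = 200L,
                     informative = 20L)
  x <- complete_beta(co)
  st <- moderated_t_stats(x, co$labels, "Grp3")
  st <- st[order(st$locus_id), ]
  in_g <- co$labels == "Grp3"
  n1 <- sum(in_g); n2 <- sum(!in_g); d <- n1 + n2 - 2L
  v1 <- apply(x[in_g, ], 2L, var)
  v2 <- apply(x[!in_g, ], 2L, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  sq <- limma::squeezeVar(s2, df = d)
  expect_equal(st$prior_df[1L], sq$df.prior, tolerance = 1e-6)
  expect_equal(st$prior_var[1L], sq$var.prior, tolerance = 1e-6)
  expect_equal(st$moderated_s2, unname(sq$var.post[st$locus_id]),
               tolerance = 1e-8)
})

test_that("moderated-t ordering equals ordinary-t ordering under equal variances", {
  # equal per-locus variance: shrinkage rescales all statistics equally
  set.seed(35)
  n <- 12L; p <- 40L
  shift <- runif(p, -0.2, 0.2)
  x <- matrix(0.5, n, p) + rep(shift, each = n)
  x <- x + matrix(rnorm(n * p, 0, 0.05), n, p)
  # make the pooled variance exactly equal across loci by standardising
  g <- rep(c("a", "b"), each = n / 2L)
  for (j in seq_len(p)) {
    for (cl in c("a", "b")) {
      i <- g == cl
      x[i, j] <- (x[i, j] - mean(x[i, j])) / sd(x[i, j]) * 0.05
    }
    x[, j] <- x[, j] + 0.5 + shift[j] * (g == "a")
  }
  dimnames(x) <- list(sprintf("s%02d", 1:n), sprintf("l%02d", 1:p))
  st <- moderated_t_stats(beta_matrix(x), g, "a")
  in_g <- g == "a"
  ordinary <- vapply(st$locus_id, function(l)
    abs(unname(t.test(x[in_g, l], x[!in_g, l], var.equal = TRUE)$statistic)),
    0)
  expect_identical(order(-abs(st$moderated_t)), order(-ordinary))
})

test_that("candidate pooling keeps top loci per contrast and honours the design filter", {
  co <- small_cohort(seed = 36L, samples = 10L, loci = 300L,
                     informative = 30L)
  x <- complete_beta(co)
  stats <- all_group_stats(x, co$labels)

  cand <- select_candidates(stats, per_group_k = 20L)
  expect_identical(length(cand$pooled), 80L)   # disjoint planted signals

  tiny <- select_candidates(stats, per_group_k = 1L)
  expect_lte(length(tiny$pooled), 4L)
  expect_identical(length(tiny$pooled),
                   length(unique(unlist(tiny$per_group))))

  # rejecting one contrast's top locus promotes its rank-21 replacement
  top_wnt <- stats$WNT$locus_id[1L]
  filt <- select_candidates(stats, per_group_k = 20L,
                            design_filter = function(id) id != top_wnt)
  expect_false(top_wnt %in% filt$pooled)
  expect_identical(filt$per_group$WNT,
                   setdiff(cand$per_group$WNT, top_wnt) |>
                     c(stats$WNT$locus_id[21L]))
  expect_true(top_wnt %in% filt$rejected$locus_id)

  expect_error(select_candidates(stats, per_group_k = 1000L), "eligible")
})

test_that("a lone separating locus is rank 1 under every base learner", {
  # two classes, one perfect separator among pure noise
  set.seed(36)
  n <- 40L
  labels2 <- rep(c("WNT", "SHH"), each = n / 2L)
  x2 <- matrix(runif(n * 15L, 0.3, 0.7), n, 15L)
  x2 <- cbind(x2, strong = ifelse(labels2 == "WNT",
                                  runif(n, 0.9, 1), runif(n, 0, 0.1)))
  colnames(x2)[1:15] <- sprintf("noise%02d", 1:15)
  rownames(x2) <- sprintf("s%02d", seq_len(n))
  scheme2 <- list(stage1 = c(WNT = "WNT", SHH = "SHH"), stage2 = NULL)
  fr2 <- fusion_rank(beta_matrix(x2), labels2, scheme = scheme2,
                     n_folds = 5L, seed = 37L)
  row <- fr2$table[fr2$table$locus_id == "strong", ]
  expect_equal(as.numeric(row[c("stage1.svm", "stage1.ann",
                                "stage1.dt", "stage1.bn")]),
               rep(1, 4L))
  expect_equal(as.numeric(row$fused_rank), 1)
})

test_that("fusion ranking favours separating loci and ignores column order", {
  set.seed(37)
  n_per <- 12L
  labels <- rep(c("WNT", "SHH", "Grp3", "Grp4"), each = n_per)
  n <- length(labels)
  p_noise <- 12L
  x <- matrix(runif(n * p_noise, 0.4, 0.6), n, p_noise)
  # one locus separating WNT from everything, plus a constant locus
  strong <- ifelse(labels == "WNT", runif(n, 0.9, 1), runif(n, 0, 0.1))
  g34 <- ifelse(labels == "Grp3", runif(n, 0.85, 1),
                ifelse(labels == "Grp4", runif(n, 0, 0.15),
                       runif(n, 0.45, 0.55)))
  shh <- ifelse(labels == "SHH", runif(n, 0.9, 1), runif(n, 0, 0.1))
  x <- cbind(x, strong = strong, g34 = g34, shh = shh,
             flat = rep(0.5, n))
  colnames(x) <- c(sprintf("noise%02d", seq_len(p_noise)),
                   "strong", "g34", "shh", "flat")
  rownames(x) <- sprintf("s%02d", seq_len(n))
  bm <- beta_matrix(x)

  fr <- fusion_rank(bm, labels, n_folds = 4L, seed = 38L)
  tab <- fr$table
  # the separating loci occupy the top of the fused ranking
  expect_true(all(tab$fused_rank[tab$locus_id %in%
                                   c("strong", "g34", "shh")] <= 3L))
  # a constant locus never beats an informative one
  expect_gt(tab$fused_rank[tab$locus_id == "flat"],
            max(tab$fused_rank[tab$locus_id %in% c("strong", "g34", "shh")]))

  # invariance to the column order of the input
  perm <- sample(ncol(x))
  fr2 <- fusion_rank(beta_matrix(x[, perm]), labels, n_folds = 4L,
                     seed = 38L)
  expect_identical(fr2$ranked_loci, fr$ranked_loci)
})

test_that("redundancy optimisation returns the requested panel unchanged when disabled", {
  co <- small_cohort(seed = 39L, samples = 10L, loci = 200L,
                     informative = 25L)
  x <- complete_beta(co)
  stats <- all_group_stats(x, co$labels)
  cand <- select_candidates(stats, per_group_k = 15L)
  xc <- beta_matrix(unclass(x)[, cand$pooled])
  fr <- fusion_rank(xc, co$labels, n_folds = 5L, seed = 40L)

  sig0 <- redundancy_optimize(fr, xc, co$labels, target_size = 17L,
                              n_iter = 0L, seed = 41L)
  expect_identical(sig0$locus_id, fr$ranked_loci[1:17])

  sig <- redundancy_optimize(fr, xc, co$labels, target_size = 17L,
                             n_iter = 8L, n_folds = 5L, seed = 41L,
                             candidates = cand)
  expect_identical(nrow(sig), 17L)
  expect_true(all(sig$locus_id %in% cand$pooled))
  expect_gte(attr(sig, "robustness"), 0.9)
})

test_that("masked accuracy does not increase with the number of masked loci", {
  fx <- trained_fixture()
  co <- fx$cohort; x <- fx$beta
  sig <- fx$signature$locus_id
  xs <- unclass(x)[, sig]
  labels <- co$labels
  model <- fx$models$signature

  complete_calls <- classify_cohort(beta_matrix(xs), model,
                                    probability_threshold = 0)$call
  set.seed(42)
  agree <- vapply(c(1L, 3L, 6L), function(j) {
    hits <- 0L; n_draws <- 80L
    for (b in seq_len(n_draws)) {
      i <- sample.int(nrow(xs), 1L)
      v <- xs[i, ]
      v[sample.int(length(v), j)] <- NA
      r <- classify_sample(v, model, probability_threshold = 0)
      hits <- hits + (r$call == complete_calls[i])
    }
    hits / n_draws
  }, 0)
  expect_true(all(diff(agree) <= 0.05 + 1e-12))
  expect_gte(agree[3L], 0.9)
})
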