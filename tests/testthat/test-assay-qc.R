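test_that("beta follows the methylated-allele proportion of extension signal", {
  expect_identical(beta_from_extension(0, 100), 0)
  expect_identical(beta_from_extension(100, 100), 0.5)
  expect_identical(beta_from_extension(0, 0), NA_real_)
  expect_error(beta_from_extension(-1, 5), ">= 0")

  # mixture-series records recover the input fraction with unit slope
  sig <- signature_definition(sprintf("mx%02d", 1:5))
  fractions <- seq(0, 1, 0.1)
  obs <- c(); input <- c()
  for (i in seq_along(fractions)) {
    rec <- simulate_assay_record(
      setNames(rep(fractions[i], 5L), sig$locus_id), sig,
      noise_sd = 0.02, seed = 60L + i)
    obs <- c(obs, beta_from_extension(rec$loci$meth, rec$loci$unmeth))
    input <- c(input, rep(fractions[i], 5L))
  }
  slope <- unname(coef(lm(obs ~ input))[2L])
  expect_equal(slope, 1, tolerance = 0.05)
})

test_that("zero-noise assay records round-trip beta exactly", {
  sig <- signature_definition(sprintf("cg%05d", 1:17))
  beta <- setNames(runif(17, 0.05, 0.95), sig$locus_id)
  rec <- simulate_assay_record(beta, sig, noise_sd = 0, seed = 1L)
  expect_equal(unname(beta_from_extension(rec$loci$meth, rec$loci$unmeth)),
               unname(beta), tolerance = 1e-12)
})

test_that("the conversion control flags incomplete bisulfite conversion", {
  sig <- signature_definition(c("a", "b"))
  mk <- function(cb) assay_record("s", c("a", "b"), c(50, 50), c(50, 50),
                                  control_beta = cb)
  expect_true(conversion_control_check(mk(0)))
  expect_false(conversion_control_check(mk(0.5)))
  expect_false(conversion_control_check(mk(NA_real_)))  # absent: conservative

  # simulated failure rate is recovered within binomial error
  n <- 150L; rate <- 0.06
  set.seed(61)
  fails <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(rate, 1 - rate))
  beta <- setNames(runif(2, 0.2, 0.8), c("a", "b"))
  flagged <- vapply(seq_len(n), function(i) {
    rec <- simulate_assay_record(beta, sig, noise_sd = 0.02,
                                 conversion_fail = fails[i])
    !conversion_control_check(rec)
  }, TRUE)
  expect_lt(abs(mean(flagged) - rate), 0.03)
})

test_that("sample QC tolerates six failed loci and applies its precedence", {
  loci <- sprintf("cg%05d", 1:17)
  mk <- function(n_fail, cb = 0.01) {
    m <- c(rep(0, n_fail), rep(60, 17L - n_fail))
    u <- c(rep(0, n_fail), rep(40, 17L - n_fail))
    assay_record("s", loci, m, u, control_beta = cb)
  }
  expect_identical(sample_qc(mk(6L))$disposition, "ANALYZABLE")
  expect_identical(sample_qc(mk(7L))$disposition, "LOCUS_QC_FAIL")
  expect_identical(sample_qc(mk(0L, cb = 0.5))$disposition, "BISULFITE_FAIL")
  # conversion failure dominates a locus-count failure
  expect_identical(sample_qc(mk(9L, cb = 0.5))$disposition, "BISULFITE_FAIL")
})

test_that("QC dispositions partition a cohort and ignore sample order", {
  sig <- signature_definition(sprintf("cg%05d", 1:17))
  set.seed(62)
  records <- lapply(1:40, function(i) {
    beta <- setNames(runif(17, 0, 1), sig$locus_id)
    beta[runif(17) < 0.25] <- NA        # heavy dropout
    simulate_assay_record(beta, sig, noise_sd = 0.02,
                          conversion_fail = runif(1) < 0.1,
                          sample_id = sprintf("P%02d", i),
                          input_ng = exp(runif(1, 0, 5)))
  })
  rep1 <- qc_report(records)
  expect_identical(sum(rep1$tally), 40L)
  expect_true(all(table(rep1$samples$disposition) ==
                    rep1$tally[rep1$tally > 0]))
  rep2 <- qc_report(rev(records))
  expect_identical(as.vector(rep1$tally), as.vector(rep2$tally))
  expect_identical(sum(as.matrix(rep1$by_input_bin)), 40L)
})

test_that("beta concordance reports R-squared, MAD and call agreement", {
  a <- matrix(runif(100, 0, 1), 20, 5,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("l%d", 1:5)))
  same <- compare_beta(a, a)
  expect_equal(same$r_squared, 1)
  expect_equal(unname(same$per_locus_mad), rep(0, 5))

  # R^2 against the variance-ratio closed form under added noise
  set.seed(63)
  av <- rbeta(4000, 2, 2)
  bv <- av + rnorm(4000, 0, 0.05)
  got <- compare_beta(av, bv)
  expected_r2 <- var(av) / (var(av) + 0.0025)
  expect_lt(abs(got$r_squared - expected_r2), 0.05)

  anti <- compare_beta(av, 1 - av)
  expect_lt(anti$slope, 0)

  calls <- compare_beta(av[1:10], av[1:10],
                        calls_a = rep(c("WNT", "SHH"), 5),
                        calls_b = c(rep("WNT", 5), rep("SHH", 5)))
  expect_equal(calls$call_agreement, 0.6)
})

test_that("beta TSV IO round-trips values and missingness and flags bad input", {
  dir <- withr::local_tempdir()
  vals <- matrix(round(runif(24), 4), 4, 6,
                 dimnames = list(sprintf("s%d", 1:4), sprintf("cg%d", 1:6)))
  vals[2, 3] <- NA; vals[4, 1] <- NA
  bm <- beta_matrix(vals)
  path <- file.path(dir, "beta.tsv")
  write_beta_tsv(bm, path)
  back <- read_beta_tsv(path)
  expect_equal(unclass(back), unclass(bm), tolerance = 1e-12)
  expect_identical(is.na(back), is.na(unclass(bm)))

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("sample_id\tcgA\tcgB", "s1\t0.5\t1.2"), bad)
  expect_error(read_beta_tsv(bad), "line 2.*cgB")
  writeLines(c("sample_id\tcgA", "s1\tx"), bad)
  expect_error(read_beta_tsv(bad), "non-numeric")
})

test_that("assay TSV IO round-trips records including the conversion control", {
  sig <- signature_definition(sprintf("cg%05d", 1:5))
  set.seed(64)
  recs <- lapply(1:3, function(i) {
    beta <- setNames(runif(5), sig$locus_id)
    if (i == 2L) beta[2L] <- NA
    simulate_assay_record(beta, sig, noise_sd = 0,
                          conversion_fail = i == 3L,
                          sample_id = sprintf("P%d", i),
                          material = "FFPE", input_ng = 10 * i)
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assay_tsv(recs, path)
  back <- read_assay_tsv(path)
  expect_identical(length(back), 3L)
  for (i in 1:3) {
    expect_equal(assay_record_beta(back[[i]]), assay_record_beta(recs[[i]]),
                 tolerance = 1e-9)
    expect_equal(back[[i]]$control_beta, recs[[i]]$control_beta,
                 tolerance = 1e-9)
    expect_identical(back[[i]]$loci$status, recs[[i]]$loci$status)
  }
  # the empty-field missing beta is seen by sample QC as a failed call
  expect_identical(sample_qc(back[[2L]], max_failed = 0L)$disposition,
                   "LOCUS_QC_FAIL")
})
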