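# Shared fixtures, built in code at test time.

# a small, fast cohort with strong planted structure
small_cohort <- function(seed = 7L, samples = 15L, loci = 400L,
                         informative = 30L, ...) {
  simulate_cohort(synthetic_config(samples_per_subgroup = samples,
                                   n_loci = loci,
                                   informative_per_subgroup = informative,
                                   seed = seed, ...))
}

# complete (median-imputed) beta matrix of a cohort
complete_beta <- function(cohort) beta_matrix(impute_locus_median(cohort$beta))

# per-subgroup moderated-t tables for a complete matrix
all_group_stats <- function(beta, labels) {
  groups <- sort(unique(as.character(labels)))
  lapply(setNames(groups, groups), function(g)
    moderated_t_stats(beta, labels, g))
}

# trained signature model on a small cohort; memoised per session because
# several test files reuse the identical fixture
trained_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- small_cohort()
    x <- complete_beta(co)
    sig <- signature_definition(top_variable_loci(x, 17L),
                                contrast = NA, plex = rep_len(1:3, 17L))
    mods <- train_models(x, co$labels, sig, n_top = 200L, seed = 5L)
    cache <<- list(cohort = co, beta = x, signature = sig, models = mods)
    cache
  }
})

# brute-force evaluation of the moderated-t formulas, written directly
# from their definition and independent of the package internals
brute_moderated_t <- function(x, in_g, d0, s02) {
  n1 <- sum(in_g); n2 <- sum(!in_g); d <- n1 + n2 - 2
  vapply(seq_len(ncol(x)), function(j) {
    a <- x[in_g, j]; b <- x[!in_g, j]
    s2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / d
    s2_mod <- (d0 * s02 + d * s2) / (d0 + d)
    (mean(a) - mean(b)) / sqrt(s2_mod * (1 / n1 + 1 / n2))
  }, 0)
}

# multivariate normal draws via Cholesky (for imputation oracles)
rmvn <- function(n, mu, sigma) {
  p <- length(mu)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% chol(sigma), 2L, mu, `+`)
}
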