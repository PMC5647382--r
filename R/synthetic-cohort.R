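#' Configuration for synthetic methylation cohorts
#'
#' Describes a cohort with planted molecular subgroup structure. Each
#' subgroup owns a set of informative loci, half hypermethylated and half
#' hypomethylated in that subgroup relative to all others; the remaining
#' loci are uninformative background. Per-sample source material (fresh
#' frozen, FFPE section, cytospin nuclear preparation) controls measurement
#' noise and locus dropout, emulating degraded archival DNA. Survival
#' times are exponential per subgroup with administrative censoring.
#'
#' Beta values are drawn from Beta distributions: hypermethylated
#' informative loci from `Beta(8, 2)` (mean 0.8), hypomethylated from
#' `Beta(2, 8)` (mean 0.2), and background loci from `Beta(2, 2)`, which
#' matches the bimodal shape of array beta-values on \eqn{[0,1]}.
#'
#' @param n_subgroups number of planted subgroups.
#' @param samples_per_subgroup integer vector (recycled) of subgroup sizes.
#' @param n_loci total number of CpG loci.
#' @param informative_per_subgroup informative loci owned by each subgroup.
#' @param beta_shape_high,beta_shape_low,background_shapes length-2 Beta
#'   shape pairs for hyper-, hypomethylated and background loci.
#' @param hyper_fraction fraction of each informative set that is
#'   hypermethylated (the rest is hypomethylated).
#' @param material_profiles data.frame with columns `material`, `noise_sd`
#'   (added truncated Gaussian noise, beta units) and `dropout` (per-locus
#'   missingness probability).
#' @param materials per-sample material assignment (recycled), drawn from
#'   `material_profiles$material`.
#' @param subgroup_names subgroup labels; defaults to the four consensus
#'   medulloblastoma subgroups when `n_subgroups == 4`.
#' @param hazard_per_subgroup exponential event rate (per month) for each
#'   subgroup; the default gives the Grp4-like group a markedly worse
#'   progression-free survival than the others.
#' @param censor_time administrative censoring time in months.
#' @param overlap_informative if `TRUE`, consecutive subgroups share 10% of
#'   their informative loci (for deduplication testing); default disjoint.
#' @param seed integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subgroups = 4L,
                             samples_per_subgroup = 50L,
                             n_loci = 5000L,
                             informative_per_subgroup = 150L,
                             beta_shape_high = c(8, 2),
                             beta_shape_low = c(2, 8),
                             background_shapes = c(2, 2),
                             hyper_fraction = 0.5,
                             material_profiles = data.frame(
                               material = c("frozen", "FFPE", "cytospin"),
                               noise_sd = c(0.01, 0.05, 0.07),
                               dropout = c(0.005, 0.10, 0.15),
                               stringsAsFactors = FALSE),
                             materials = "frozen",
                             subgroup_names = NULL,
                             hazard_per_subgroup = NULL,
                             censor_time = 60,
                             overlap_informative = FALSE,
                             seed = 1L) {
  n_subgroups <- as.integer(n_subgroups)
  if (n_subgroups < 2L) stop("need at least two subgroups")
  shapes <- c(beta_shape_high, beta_shape_low, background_shapes)
  if (length(shapes) != 6L || any(!is.finite(shapes)) || any(shapes <= 0))
    stop("Beta shape parameters must be positive")
  if (any(material_profiles$dropout < 0 | material_profiles$dropout > 1))
    stop("dropout probabilities must lie in [0,1]")
  if (any(material_profiles$noise_sd < 0))
    stop("noise_sd must be non-negative")
  if (informative_per_subgroup * n_subgroups > n_loci)
    stop("informative_per_subgroup x n_subgroups exceeds n_loci")
  if (is.null(subgroup_names))
    subgroup_names <- if (n_subgroups == 4L) c("WNT", "SHH", "Grp3", "Grp4")
                      else paste0("G", seq_len(n_subgroups))
  if (length(subgroup_names) != n_subgroups)
    stop("subgroup_names length mismatch")
  sizes <- rep_len(as.integer(samples_per_subgroup), n_subgroups)
  materials <- rep_len(as.character(materials), sum(sizes))
  if (!all(materials %in% material_profiles$material))
    stop("unknown material in 'materials'")
  if (is.null(hazard_per_subgroup)) {
    ## ~95% 5-year PFS for most groups, ~82% for the last (Grp4-like) one
    hazard_per_subgroup <- rep(-log(0.95) / 60, n_subgroups)
    hazard_per_subgroup[n_subgroups] <- -log(0.82) / 60
  }
  hazard_per_subgroup <- rep_len(hazard_per_subgroup, n_subgroups)
  if (any(hazard_per_subgroup < 0)) stop("hazards must be non-negative")
  cfg <- list(n_subgroups = n_subgroups,
              samples_per_subgroup = sizes,
              n_loci = as.integer(n_loci),
              informative_per_subgroup = as.integer(informative_per_subgroup),
              beta_shape_high = beta_shape_high,
              beta_shape_low = beta_shape_low,
              background_shapes = background_shapes,
              hyper_fraction = hyper_fraction,
              material_profiles = material_profiles,
              materials = materials,
              subgroup_names = subgroup_names,
              hazard_per_subgroup = setNames(hazard_per_subgroup, subgroup_names),
              censor_time = censor_time,
              overlap_informative = isTRUE(overlap_informative),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate a methylation cohort with planted subgroups
#'
#' Generates a beta-value matrix, ground-truth subgroup labels, per-sample
#' material tags, survival records and the planted informative locus sets.
#' With a fixed seed the whole cohort is bit-identical across runs.
#'
#' @param config a [synthetic_config()].
#' @param informative_loci optional informative-locus structure from a
#'   previous cohort (its `informative_loci` element): the new cohort is
#'   then drawn from the same population, which is how independent
#'   validation and test cohorts are simulated.
#' @return a list of class `synthetic_cohort` with elements `beta`
#'   ([beta_matrix()]), `labels` (factor), `material`, `survival`
#'   (data.frame: `sample_id`, `time_months`, `event`, `group`),
#'   `informative_loci` (per-subgroup list with `hyper` and `hypo` sets)
#'   and `config`.
#' @export
simulate_cohort <- function(config = synthetic_config(),
                            informative_loci = NULL) {
  if (!inherits(config, "synthetic_config"))
    stop("'config' must be a synthetic_config")
  set.seed(config$seed)
  n <- sum(config$samples_per_subgroup)
  p <- config$n_loci
  groups <- config$subgroup_names
  labels <- factor(rep(groups, config$samples_per_subgroup), levels = groups)
  sample_ids <- sprintf("S%03d", seq_len(n))
  locus_ids <- sprintf("cg%05d", seq_len(p))

  ## partition informative loci (optionally with 10% overlap between
  ## consecutive subgroups, for deduplication tests)
  k_inf <- config$informative_per_subgroup
  pool <- sample(locus_ids, config$n_subgroups * k_inf)
  informative <- vector("list", config$n_subgroups)
  names(informative) <- groups
  if (!is.null(informative_loci)) {
    if (!all(unlist(informative_loci) %in% locus_ids))
      stop("supplied informative loci are not part of this locus universe")
    informative <- informative_loci[groups]
  } else for (g in seq_len(config$n_subgroups)) {
    own <- if (k_inf > 0L) pool[((g - 1L) * k_inf + 1L):(g * k_inf)]
           else character(0)
    if (config$overlap_informative && g > 1L) {
      n_shared <- floor(k_inf / 10)
      prev <- informative[[g - 1L]]
      own[seq_len(n_shared)] <- c(prev$hyper, prev$hypo)[seq_len(n_shared)]
    }
    n_hyper <- round(config$hyper_fraction * length(own))
    informative[[g]] <- list(hyper = own[seq_len(n_hyper)],
                             hypo = own[setdiff(seq_along(own),
                                                seq_len(n_hyper))])
  }

  ## background everywhere, then overwrite informative columns
  vals <- matrix(rbeta(n * p, config$background_shapes[1L],
                       config$background_shapes[2L]), n, p,
                 dimnames = list(sample_ids, locus_ids))
  hi <- config$beta_shape_high
  lo <- config$beta_shape_low
  for (g in seq_len(config$n_subgroups)) {
    in_g <- labels == groups[g]
    hyp <- informative[[g]]$hyper
    hpo <- informative[[g]]$hypo
    vals[in_g, hyp] <- rbeta(sum(in_g) * length(hyp), hi[1L], hi[2L])
    vals[!in_g, hyp] <- rbeta(sum(!in_g) * length(hyp), lo[1L], lo[2L])
    vals[in_g, hpo] <- rbeta(sum(in_g) * length(hpo), lo[1L], lo[2L])
    vals[!in_g, hpo] <- rbeta(sum(!in_g) * length(hpo), hi[1L], hi[2L])
  }

  ## material-specific measurement noise and dropout
  prof <- config$material_profiles
  material <- setNames(config$materials, sample_ids)
  for (m in unique(material)) {
    rows <- which(material == m)
    pr <- prof[prof$material == m, ]
    if (pr$noise_sd > 0)
      vals[rows, ] <- clip01(vals[rows, ] +
                               rnorm(length(rows) * p, 0, pr$noise_sd))
    if (pr$dropout > 0) {
      drop <- matrix(runif(length(rows) * p) < pr$dropout, length(rows), p)
      vals[rows, ][drop] <- NA_real_
    }
  }

  surv <- simulate_survival(labels, config$hazard_per_subgroup,
                            censor_time = config$censor_time,
                            sample_ids = sample_ids)
  out <- list(beta = beta_matrix(vals, sample_ids, locus_ids),
              labels = setNames(labels, sample_ids),
              material = material,
              survival = surv,
              informative_loci = informative,
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples x %d loci, %d subgroups (%s)\n",
              nrow(x$beta), ncol(x$beta), x$config$n_subgroups,
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

#' Simulate a primer-extension assay record from a beta vector
#'
#' Emulates the in-silico statistics of a multiplexed single-base extension
#' readout: each signature locus yields a methylated/unmethylated intensity
#' pair `(m, u)` with `m/(m+u)` equal to the input beta plus truncated
#' Gaussian noise clipped to \eqn{[0,1]}. Missing beta entries become
#' failed calls (zero intensities, `NO_CALL`). The bisulfite conversion
#' control targets an invariably unmethylated locus: its apparent beta is
#' near zero on success and well above the control cut-off when
#' `conversion_fail = TRUE`.
#'
#' @param beta_row named numeric vector of beta values (may contain `NA`)
#'   covering the signature loci.
#' @param signature a [signature_definition()] (or locus id vector).
#' @param noise_sd Gaussian noise standard deviation on the beta scale.
#' @param conversion_fail simulate a failed bisulfite conversion.
#' @param seed optional integer seed.
#' @param sample_id,material,input_ng record metadata.
#' @param total_intensity arbitrary summed intensity per locus.
#' @return a list of class `assay_record`; see [assay_record()].
#' @export
simulate_assay_record <- function(beta_row, signature,
                                  noise_sd = 0.02,
                                  conversion_fail = FALSE,
                                  seed = NULL,
                                  sample_id = "sample",
                                  material = "frozen",
                                  input_ng = NA_real_,
                                  total_intensity = 1e4) {
  if (!is.null(seed)) set.seed(seed)
  loci <- signature_loci(signature)
  beta <- beta_row[loci]
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta values must lie in [0,1] or be missing")
  obs <- clip01(beta + if (noise_sd > 0) rnorm(length(beta), 0, noise_sd) else 0)
  m <- ifelse(is.na(obs), 0, total_intensity * obs)
  u <- ifelse(is.na(obs), 0, total_intensity * (1 - obs))
  status <- ifelse(is.na(obs), "NO_CALL", "OK")
  control_beta <- if (conversion_fail) runif(1, 0.3, 0.8) else runif(1, 0, 0.02)
  assay_record(sample_id = sample_id,
               locus_id = loci, meth = m, unmeth = u, status = status,
               control_beta = control_beta,
               material = material, input_ng = input_ng)
}

#' Simulate a control-DNA methylation mixture series
#'
#' Emulates the triplicate mixture series of fully methylated and fully
#' unmethylated control DNA used to validate each amplicon: for each input
#' methylation fraction, each locus reports that fraction plus truncated
#' Gaussian noise. The result supports the per-locus linearity check used
#' to accept or reject amplicons during iterative signature redesign.
#'
#' @param fractions methylation proportions in \eqn{[0,1]}.
#' @param loci locus identifiers (or a [signature_definition()]).
#' @param replicates replicates per fraction.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed optional integer seed.
#' @return a [beta_matrix()] with one row per fraction x replicate; the
#'   input fraction is recorded in attribute `fraction`.
#' @export
simulate_mixture_series <- function(fractions = seq(0, 1, 0.25),
                                    loci = sprintf("cg%05d", 1:17),
                                    replicates = 3L,
                                    noise_sd = 0.02,
                                    seed = NULL) {
  if (!length(fractions)) stop("'fractions' must be non-empty")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  loci <- signature_loci(loci)
  frac <- rep(fractions, each = replicates)
  n <- length(frac)
  vals <- matrix(rep(frac, times = length(loci)), n, length(loci))
  if (noise_sd > 0)
    vals <- vals + rnorm(n * length(loci), 0, noise_sd)
  vals <- clip01(vals)
  ids <- sprintf("mix%02d_r%d", rep(seq_along(fractions), each = replicates),
                 rep(seq_len(replicates), length(fractions)))
  out <- beta_matrix(vals, ids, loci)
  attr(out, "fraction") <- setNames(frac, ids)
  out
}

#' Simulate subgroup-dependent survival records
#'
#' Event times are exponential with a per-subgroup hazard; times beyond
#' `censor_time` are administratively censored at `censor_time`. A hazard
#' of zero yields an all-censored subgroup.
#'
#' @param labels subgroup label per sample.
#' @param hazards named (or positionally matched) per-subgroup event rates,
#'   per month; must be non-negative.
#' @param censor_time administrative censoring time in months.
#' @param seed optional integer seed.
#' @param sample_ids sample identifiers.
#' @return data.frame with `sample_id`, `time_months`, `event` (1 = event,
#'   0 = censored) and `group`.
#' @export
simulate_survival <- function(labels, hazards, censor_time = 60,
                              seed = NULL,
                              sample_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.factor(labels)
  groups <- levels(labels)
  if (is.null(names(hazards))) {
    if (length(hazards) != length(groups))
      stop("need one hazard per subgroup")
    hazards <- setNames(rep_len(hazards, length(groups)), groups)
  }
  if (!all(groups %in% names(hazards))) stop("need one hazard per subgroup")
  if (any(hazards < 0)) stop("hazards must be non-negative")
  lam <- unname(hazards[as.character(labels)])
  times <- ifelse(lam > 0, rexp(length(lam), rate = pmax(lam, 1e-300)), Inf)
  event <- as.integer(times <= censor_time)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_along(labels))
  data.frame(sample_id = sample_ids,
             time_months = pmin(times, censor_time),
             event = event,
             group = as.character(labels),
             stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `beta.tsv` (samples x loci, empty field = missing), `labels.tsv`
#' (`sample_id`, `label`, `material`), `survival.tsv` and `config.json`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write.table(data.frame(sample_id = names(cohort$labels),
                         label = as.character(cohort$labels),
                         material = unname(cohort$material)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$survival, file.path(dir, "survival.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$material_profiles <- as.data.frame(cfg$material_profiles)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
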