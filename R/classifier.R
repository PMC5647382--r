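#' Train the genome-scale and signature subgroup classifiers
#'
#' Trains the two support vector machine models used by the pipeline: a
#' genome-scale model on the `n_top` most variably methylated loci of the
#' training matrix, and a minimal-signature model on exactly the signature
#' loci. Both are linear-kernel SVMs (one-vs-one) with pairwise-coupled
#' probability calibration, so every prediction carries calibrated class
#' probabilities summing to one. The signature model additionally stores
#' the training mean vector and ridge-regularised covariance of the
#' logit-transformed signature betas, which drive expectation-maximisation
#' imputation of missing loci at classification time, plus the two shipped
#' thresholds: at most `max_missing` missing loci (default 6) and a
#' classification confidence threshold (default 0.69) below which samples
#' are non-classifiable.
#'
#' @param beta training [beta_matrix()].
#' @param labels subgroup label per sample; all classes must be present.
#' @param signature a [signature_definition()] whose loci are all columns
#'   of `beta`.
#' @param n_top loci kept for the genome-scale model.
#' @param max_missing maximum tolerated missing signature loci.
#' @param probability_threshold confidence threshold for classification.
#' @param ridge covariance ridge for the imputation model.
#' @param seed integer seed (internal probability-calibration CV).
#' @return list with `full` and `signature`, each of class
#'   `subgroup_model`.
#' @export
train_models <- function(beta, labels, signature, n_top = 10000L,
                         max_missing = 6L, probability_threshold = 0.69,
                         ridge = 1e-3, seed = 1L) {
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2L) stop("need at least two classes")
  if (any(table(labels) < 2L)) stop("every class needs >= 2 samples")
  sig_loci <- signature_loci(signature)
  if (!all(sig_loci %in% colnames(beta)))
    stop("signature loci absent from the training matrix: ",
         paste(setdiff(sig_loci, colnames(beta)), collapse = ", "))

  x <- impute_locus_median(beta)
  full_loci <- top_variable_loci(beta, n_top)
  full <- fit_subgroup_model(x[, full_loci, drop = FALSE], labels,
                             kind = "full_450k", seed = seed,
                             max_missing = max_missing,
                             probability_threshold = probability_threshold)

  xs <- x[, sig_loci, drop = FALSE]
  sig_model <- fit_subgroup_model(xs, labels, kind = "signature",
                                  seed = seed, max_missing = max_missing,
                                  probability_threshold = probability_threshold)
  z <- logit2(xs)
  sig_model$imputation <- list(mean = colMeans(z),
                               cov = ridge_cov(z, ridge),
                               ridge = ridge)
  sig_model$signature <- if (inherits(signature, "signature_def")) signature
                         else signature_definition(sig_loci)
  list(full = full, signature = sig_model)
}

fit_subgroup_model <- function(x, labels, kind, seed, max_missing,
                               probability_threshold) {
  set.seed(seed)     # probability calibration uses internal CV
  fit <- e1071::svm(x, labels, kernel = "linear", scale = FALSE, cost = 1,
                    probability = TRUE)
  model <- list(model_kind = kind,
                loci = colnames(x),
                svm = fit,
                classes = levels(labels),
                feature_medians = apply(x, 2L, median),
                max_missing = as.integer(max_missing),
                probability_threshold = probability_threshold,
                imputation = NULL,
                signature = NULL)
  class(model) <- "subgroup_model"
  model
}

#' @export
print.subgroup_model <- function(x, ...) {
  cat(sprintf(
    "subgroup_model (%s): %d loci, classes %s; max_missing = %d, threshold = %.2f\n",
    x$model_kind, length(x$loci), paste(x$classes, collapse = "/"),
    x$max_missing, x$probability_threshold))
  invisible(x)
}

ridge_cov <- function(z, ridge) {
  s <- stats::cov(z)
  s + diag(ridge, ncol(z))
}

## calibrated class probabilities for a feature matrix, columns ordered as
## model$classes; rows sum to 1
predict_probabilities <- function(model, x) {
  pr <- predict(model$svm, x, probability = TRUE)
  p <- attr(pr, "probabilities")[, model$classes, drop = FALSE]
  p / rowSums(p)
}

#' Impute missing signature loci by expectation-maximisation
#'
#' Treats the logit-transformed signature beta vector as multivariate
#' normal with the training mean and (ridge-regularised) covariance stored
#' in the model, and iterates expected-value updates of the missing
#' coordinates -- each missing entry is replaced by its Gaussian
#' conditional mean given all other current values -- until convergence.
#' The fixed point is the joint conditional expectation of the missing
#' block given the observed block. Observed entries are never altered and
#' imputed values are mapped back into \eqn{[0,1]}.
#'
#' @param x named beta vector over the signature loci; `NA` = missing.
#' @param model the signature [train_models()] model.
#' @param max_iter,tol convergence control for the EM sweeps.
#' @return the completed beta vector.
#' @export
impute_missing_em <- function(x, model, max_iter = 100L, tol = 1e-10) {
  if (is.null(model$imputation))
    stop("model carries no imputation statistics (train a signature model)")
  loci <- model$loci
  x <- x[loci]
  miss <- which(is.na(x))
  if (!length(miss)) return(x)
  if (length(miss) > model$max_missing) {
    cond <- structure(class = c("minsig_locus_qc_fail", "error", "condition"),
                      list(message = sprintf(
                        "%d missing loci exceed the tolerated maximum of %d",
                        length(miss), model$max_missing),
                        call = sys.call(-1L)))
    stop(cond)
  }
  mu <- model$imputation$mean
  sig <- model$imputation$cov
  z <- logit2(x)
  z[miss] <- mu[miss]
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in miss) {
      s_jo <- sig[j, -j, drop = FALSE]
      new <- mu[j] + s_jo %*% solve(sig[-j, -j], z[-j] - mu[-j])
      delta <- max(delta, abs(new - z[j]))
      z[j] <- new
    }
    if (delta < tol) break
  }
  out <- x
  out[miss] <- clip01(inv_logit2(z[miss]))
  out
}

#' Calibrate the maximum tolerated number of missing loci
#'
#' Bootstrap procedure: for each candidate number of missing loci `j` from
#' 0 to one less than the signature size, resample validation samples with
#' replacement `n_boot` times in total, mask `j` randomly chosen signature
#' loci in each draw, impute and classify, and record agreement with the
#' complete-data calls. The agreement curve is made monotone non-increasing
#' (cumulative minimum) before thresholding; the calibrated threshold is
#' the largest `j` whose smoothed agreement is at least `tolerance`.
#'
#' @param model signature model from [train_models()].
#' @param beta validation [beta_matrix()] containing the signature loci.
#' @param n_boot total bootstrap draws per candidate `j`.
#' @param tolerance required agreement with complete-data calls.
#' @param seed integer seed.
#' @return integer threshold in `0 .. signature_size - 1`, with the
#'   agreement curve attached as attribute `agreement`.
#' @export
calibrate_missing_threshold <- function(model, beta, n_boot = 10000L,
                                        tolerance = 0.99, seed = 1L) {
  if (!nrow(beta)) stop("empty validation set")
  set.seed(seed)
  x <- impute_locus_median(beta)[, model$loci, drop = FALSE]
  p <- length(model$loci)
  complete_calls <- model$classes[max.col(predict_probabilities(model, x))]
  agree <- numeric(p)
  saved_max <- model$max_missing
  model$max_missing <- p          # calibration explores the whole range
  for (j in 0:(p - 1L)) {
    hits <- 0L
    rows <- sample.int(nrow(x), n_boot, replace = TRUE)
    for (b in seq_len(n_boot)) {
      xi <- x[rows[b], ]
      if (j > 0L) xi[sample.int(p, j)] <- NA_real_
      xi <- impute_missing_em(xi, model)
      pr <- predict_probabilities(model, matrix(xi, 1L,
                                                dimnames = list(NULL, model$loci)))
      hits <- hits + (model$classes[which.max(pr)] == complete_calls[rows[b]])
    }
    agree[j + 1L] <- hits / n_boot
  }
  model$max_missing <- saved_max
  smoothed <- cummin(agree)
  ok <- which(smoothed >= tolerance)
  threshold <- if (length(ok)) max(ok) - 1L else 0L
  structure(as.integer(threshold),
            agreement = data.frame(n_missing = 0:(p - 1L), agreement = agree,
                                   smoothed = smoothed))
}

#' Calibrate the classification confidence threshold
#'
#' Grid search: the calibrated threshold is the smallest grid value `t`
#' such that, among validation samples whose maximum class probability is
#' at least `t`, the misclassification rate does not exceed `tolerance`
#' (default 0: no errors above the threshold). When calibration is not
#' performed, models ship with the default threshold of 0.69.
#'
#' @param probabilities samples x classes probability matrix (or a vector
#'   of maximum probabilities).
#' @param predicted predicted class per sample (derived from
#'   `probabilities` when it is a matrix and `predicted` is `NULL`).
#' @param truth reference label per sample.
#' @param grid candidate thresholds.
#' @param tolerance highest acceptable misclassification rate above the
#'   threshold.
#' @return the calibrated threshold.
#' @export
calibrate_probability_threshold <- function(probabilities, truth,
                                            predicted = NULL,
                                            grid = seq(0, 1, by = 0.01),
                                            tolerance = 0) {
  if (is.matrix(probabilities)) {
    if (is.null(predicted))
      predicted <- colnames(probabilities)[max.col(probabilities)]
    maxp <- apply(probabilities, 1L, max)
  } else {
    maxp <- probabilities
    if (is.null(predicted)) stop("'predicted' required with a vector input")
  }
  correct <- predicted == as.character(truth)
  for (t in sort(grid)) {
    above <- maxp >= t
    if (!any(above)) break
    if (mean(!correct[above]) <= tolerance) return(t)
  }
  stop("no grid threshold achieves the requested tolerance ",
       "(all samples fall below every feasible grid point)")
}

#' Classify a single sample through the QC cascade
#'
#' Applies, in order: (1) bisulfite conversion control -- a failed control
#' gives `FAIL` with code `BISULFITE_FAIL` regardless of locus data;
#' (2) the missing-loci rule -- more than `max_missing` failed signature
#' loci gives `FAIL` with code `LOCUS_QC_FAIL`; (3) otherwise missing loci
#' are EM-imputed, calibrated class probabilities computed, and a maximum
#' probability below the confidence threshold yields `NC`
#' (`BELOW_THRESHOLD`) while a confident call returns the argmax class
#' with code `PASS`. Classification is deterministic given the model and
#' input.
#'
#' @param x an [assay_record()] or a named beta vector covering the
#'   signature loci (`NA` = missing).
#' @param model signature model from [train_models()].
#' @param probability_threshold,max_missing optional overrides of the
#'   shipped thresholds.
#' @param control_cutoff conversion-control cut-off (apparent beta) used
#'   when `x` is an assay record.
#' @return a list of class `classification_result`: `call` (subgroup, `NC`
#'   or `FAIL`), `probabilities`, `probability` (of the call),
#'   `n_missing`, `qc_code`.
#' @export
classify_sample <- function(x, model,
                            probability_threshold = model$probability_threshold,
                            max_missing = model$max_missing,
                            control_cutoff = 0.1) {
  sample_id <- NA_character_
  if (inherits(x, "assay_record")) {
    sample_id <- x$sample_id
    if (!conversion_control_check(x, cutoff = control_cutoff))
      return(classification_result("FAIL", NULL, NA_integer_,
                                   "BISULFITE_FAIL", sample_id))
    x <- assay_record_beta(x)
  }
  if (!all(model$loci %in% names(x)))
    stop("input vector does not cover the signature loci")
  x <- x[model$loci]
  n_missing <- sum(is.na(x))
  if (n_missing > max_missing)
    return(classification_result("FAIL", NULL, n_missing,
                                 "LOCUS_QC_FAIL", sample_id))
  xi <- x
  if (n_missing > 0L) {
    if (is.null(model$imputation)) {
      ## genome-scale model: no tractable joint model at 10,000 loci;
      ## missing features fall back to training medians
      miss <- is.na(xi)
      xi[miss] <- model$feature_medians[names(xi)[miss]]
    } else {
      model$max_missing <- max_missing
      xi <- impute_missing_em(x, model)
    }
  }
  pr <- predict_probabilities(model, matrix(xi, 1L,
                                            dimnames = list(NULL, model$loci)))
  probs <- setNames(as.numeric(pr), colnames(pr))
  top <- which.max(probs)
  if (probs[top] < probability_threshold)
    return(classification_result("NC", probs, n_missing,
                                 "BELOW_THRESHOLD", sample_id))
  classification_result(names(probs)[top], probs, n_missing, "PASS",
                        sample_id)
}

classification_result <- function(call, probabilities, n_missing, qc_code,
                                  sample_id = NA_character_) {
  out <- list(sample_id = sample_id,
              call = call,
              probabilities = probabilities,
              probability = if (is.null(probabilities)) NA_real_
                            else max(probabilities),
              n_missing = n_missing,
              qc_code = qc_code)
  class(out) <- "classification_result"
  out
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("call: %s (qc: %s, p = %s, missing loci: %s)\n",
              x$call, x$qc_code,
              ifelse(is.na(x$probability), "-",
                     sprintf("%.3f", x$probability)),
              ifelse(is.na(x$n_missing), "-", x$n_missing)))
  invisible(x)
}

#' Classify every row of a beta matrix
#'
#' @param beta [beta_matrix()] covering the signature loci.
#' @param model signature model from [train_models()].
#' @param ... passed to [classify_sample()].
#' @return data.frame with `sample_id`, `call`, `probability`,
#'   `n_missing`, `qc_code` plus one probability column per class.
#' @export
classify_cohort <- function(beta, model, ...) {
  res <- lapply(rownames(beta), function(s) {
    r <- classify_sample(setNames(as.numeric(beta[s, model$loci]),
                                  model$loci), model, ...)
    r$sample_id <- s
    r
  })
  calls_table(res)
}

calls_table <- function(results) {
  classes <- NULL
  for (r in results)
    if (!is.null(r$probabilities)) { classes <- names(r$probabilities); break }
  df <- data.frame(sample_id = vapply(results, `[[`, "", "sample_id"),
                   call = vapply(results, `[[`, "", "call"),
                   probability = vapply(results, `[[`, 0, "probability"),
                   n_missing = vapply(results, function(r)
                     as.integer(r$n_missing), 0L),
                   qc_code = vapply(results, `[[`, "", "qc_code"),
                   stringsAsFactors = FALSE)
  for (cl in classes)
    df[[cl]] <- vapply(results, function(r)
      if (is.null(r$probabilities)) NA_real_ else r$probabilities[[cl]], 0)
  df
}

#' Serialise / restore a signature model as versioned JSON
#'
#' Model parameters (support vectors, coefficients, probability
#' calibration), imputation statistics and thresholds are written as a
#' versioned JSON document rather than an opaque binary, so shipped models
#' are auditable. `read_model_json` reconstructs a functional model.
#'
#' @param model a signature `subgroup_model`.
#' @param path file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the restored `subgroup_model`.
#' @export
write_model_json <- function(model, path) {
  fit <- model$svm
  obj <- list(format = "minsig-model", version = 1L,
              model_kind = model$model_kind,
              loci = model$loci,
              classes = model$classes,
              max_missing = model$max_missing,
              probability_threshold = model$probability_threshold,
              feature_medians = as.list(model$feature_medians),
              imputation = if (is.null(model$imputation)) NULL else list(
                mean = as.list(model$imputation$mean),
                cov = model$imputation$cov,
                ridge = model$imputation$ridge),
              signature = if (is.null(model$signature)) NULL
                          else as.data.frame(model$signature),
              svm = list(SV = unclass(fit$SV),
                         coefs = fit$coefs,
                         rho = fit$rho,
                         probA = fit$probA,
                         probB = fit$probB,
                         labels = fit$labels,
                         nSV = fit$nSV,
                         levels = levels(fit$fitted),
                         gamma = fit$gamma,
                         cost = fit$cost))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "minsig-model"))
    stop("not a minsig model file")
  ## rebuild by refitting is not possible from JSON alone; restore the
  ## svm object fields libsvm prediction needs
  sv <- as.matrix(obj$svm$SV)
  storage.mode(sv) <- "double"
  colnames(sv) <- obj$loci
  fit <- structure(list(
    SV = sv,
    coefs = as.matrix(obj$svm$coefs),
    rho = as.numeric(obj$svm$rho),
    probA = as.numeric(obj$svm$probA),
    probB = as.numeric(obj$svm$probB),
    labels = as.integer(obj$svm$labels),
    nSV = as.integer(obj$svm$nSV),
    gamma = obj$svm$gamma,
    cost = obj$svm$cost,
    type = 0L, kernel = 0L, degree = 3L, coef0 = 0,
    nu = 0.5, epsilon = 0.1,
    sparse = FALSE, scaled = rep(FALSE, ncol(sv)),
    x.scale = NULL, y.scale = NULL,
    tot.nSV = sum(as.integer(obj$svm$nSV)),
    levels = obj$svm$levels,
    nclasses = length(obj$svm$levels),
    compprob = TRUE,
    fitted = NULL, na.action = stats::na.omit),
    class = "svm")
  model <- list(model_kind = obj$model_kind,
                loci = obj$loci,
                svm = fit,
                classes = obj$classes,
                feature_medians = unlist(obj$feature_medians),
                max_missing = as.integer(obj$max_missing),
                probability_threshold = obj$probability_threshold,
                imputation = if (is.null(obj$imputation)) NULL else list(
                  mean = unlist(obj$imputation$mean),
                  cov = {
                    m <- as.matrix(obj$imputation$cov)
                    storage.mode(m) <- "double"
                    dimnames(m) <- list(obj$loci, obj$loci)
                    m
                  },
                  ridge = obj$imputation$ridge),
                signature = if (is.null(obj$signature)) NULL else
                  signature_definition(obj$signature$locus_id,
                                       contrast = obj$signature$contrast,
                                       plex = obj$signature$plex,
                                       chrom = obj$signature$chrom,
                                       pos = obj$signature$pos))
  class(model) <- "subgroup_model"
  model
}
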