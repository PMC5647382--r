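#' Non-negative matrix factorisation of a beta matrix
#'
#' Factorises the loci x samples matrix `V` as `V ~ W H` with `W` (loci x
#' k, the metagene basis) and `H` (k x samples, metagene coefficients), by
#' Lee-Seung multiplicative updates minimising the Frobenius
#' reconstruction error. The objective is non-increasing across updates;
#' iteration stops when the relative decrease falls below `tol` or after
#' `max_iter` updates. Each sample is assigned to the metagene with the
#' largest coefficient.
#'
#' @param beta a [beta_matrix()] (samples x loci) with no missing values;
#'   impute first (e.g. [impute_locus_median()] via [consensus_cluster()]).
#' @param k factorisation rank (>= 1).
#' @param seed integer seed for the random initialisation.
#' @param max_iter,tol stopping rule.
#' @return list with `basis` (loci x k), `coef` (k x samples),
#'   `assignments` (named integer per sample), `objective` (trace of the
#'   Frobenius error per iteration).
#' @export
nmf_factorize <- function(beta, k, seed = 1L, max_iter = 200L, tol = 1e-4) {
  if (anyNA(beta))
    stop("beta matrix contains missing values; impute before factorisation")
  if (k < 1L) stop("rank k must be >= 1")
  v <- t(unclass_beta(beta))           # loci x samples
  if (any(v < 0)) stop("all values must be non-negative")
  set.seed(seed)
  p <- nrow(v); n <- ncol(v)
  w <- matrix(runif(p * k, 0.1, 1), p, k) * mean(v)
  h <- matrix(runif(k * n, 0.1, 1), k, n)
  eps <- .Machine$double.eps
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, v) / (crossprod(w) %*% h + eps))
    w <- w * ((v %*% t(h)) / (w %*% tcrossprod(h) + eps))
    err <- sqrt(sum((v - w %*% h)^2))
    obj <- c(obj, err)
    if (is.finite(prev) && (prev - err) < tol * max(prev, eps)) break
    prev <- err
  }
  assignments <- apply(h, 2L, which.max)
  names(assignments) <- rownames(beta)
  dimnames(w) <- list(colnames(beta), paste0("metagene", seq_len(k)))
  dimnames(h) <- list(paste0("metagene", seq_len(k)), rownames(beta))
  list(basis = w, coef = h, assignments = assignments, objective = obj)
}

#' NMF consensus clustering with rank selection
#'
#' Repeatedly factorises random subsamples of the cohort at each candidate
#' rank `k`, accumulates the frequency with which each pair of samples is
#' co-assigned to the same metagene (the consensus matrix), and selects the
#' rank whose consensus matrix has the highest cophenetic correlation
#' (mean silhouette width breaks ties). Final assignments at the selected
#' rank come from average-linkage hierarchical clustering of the consensus
#' dissimilarity `1 - C`.
#'
#' Missing beta values are filled with locus medians before factorisation,
#' and clustering runs on the `n_top_loci` most variably methylated loci.
#' Samples are internally ordered by identifier, so the partition is
#' invariant to the input sample order.
#'
#' @param beta a [beta_matrix()].
#' @param k_range candidate ranks (must fit within `n_samples / 3`).
#' @param n_restarts random restarts per rank (>= 10).
#' @param subsample fraction of samples drawn (without replacement) per
#'   restart.
#' @param n_top_loci variable-loci pre-filter applied before clustering.
#' @param seed integer seed.
#' @param max_iter,tol passed to [nmf_factorize()].
#' @param cophenetic_tol ranks whose cophenetic coefficient lies within
#'   this distance of the maximum are treated as tied and resolved by
#'   mean silhouette width. The cophenetic coefficient saturates towards 1
#'   on cohorts with well-separated subgroups, where overfactorised ranks
#'   can exceed the true rank by a sliver; the silhouette tie-break then
#'   carries the decision.
#' @return a list of class `consensus_result`: `k_selected`, `assignments`
#'   (named, at `k_selected`), `per_k` (per-rank consensus matrix,
#'   cophenetic coefficient, mean silhouette width, assignments), `basis`
#'   and `coef` from a full-data factorisation at `k_selected`, and
#'   `metrics` (a per-rank summary data.frame).
#' @export
consensus_cluster <- function(beta, k_range = 2:8, n_restarts = 50L,
                              subsample = 0.8, n_top_loci = 10000L,
                              seed = 1L, max_iter = 100L, tol = 1e-4,
                              cophenetic_tol = 0.01) {
  n <- nrow(beta)
  if (length(k_range) < 1L || any(k_range < 2L))
    stop("k_range must contain ranks >= 2")
  if (max(k_range) > n / 3)
    stop("largest rank exceeds n_samples / 3")
  if (n_restarts < 10L) stop("n_restarts must be >= 10")

  ## canonical sample order => permutation-invariant partition
  ord <- order(rownames(beta))
  x <- impute_locus_median(beta)[ord, , drop = FALSE]
  keep <- top_variable_loci(beta_matrix(x), n_top_loci)
  x <- x[, keep, drop = FALSE]
  ids <- rownames(x)

  n_sub <- max(2L, floor(subsample * n))
  per_k <- list()
  for (k in k_range) {
    co <- matrix(0, n, n)
    cnt <- matrix(0, n, n)
    for (r in seq_len(n_restarts)) {
      run_seed <- (seed * 100000L + k * 1000L + r) %% .Machine$integer.max
      set.seed(run_seed)
      idx <- sort(sample.int(n, n_sub))
      fit <- nmf_factorize(beta_matrix(x[idx, , drop = FALSE]), k,
                           seed = run_seed, max_iter = max_iter, tol = tol)
      a <- fit$assignments
      same <- outer(a, a, "==") * 1
      co[idx, idx] <- co[idx, idx] + same
      cnt[idx, idx] <- cnt[idx, idx] + 1
    }
    cons <- ifelse(cnt > 0, co / pmax(cnt, 1), 0)
    diag(cons) <- 1
    cons <- (cons + t(cons)) / 2
    dimnames(cons) <- list(ids, ids)
    d <- as.dist(1 - cons)
    hc <- hclust(d, method = "average")
    coph <- suppressWarnings(cor(d, cophenetic(hc)))
    if (is.na(coph)) coph <- 0
    assign_k <- cutree(hc, k = k)
    sil <- tryCatch(silhouette_widths(1 - cons, assign_k),
                    error = function(e) rep(0, n))
    per_k[[as.character(k)]] <- list(consensus = cons,
                                     cophenetic = coph,
                                     mean_silhouette = mean(sil),
                                     assignments = assign_k)
  }

  metrics <- data.frame(k = k_range,
                        cophenetic = vapply(per_k, `[[`, 0, "cophenetic"),
                        mean_silhouette = vapply(per_k, `[[`, 0,
                                                 "mean_silhouette"))
  tied <- metrics$cophenetic >= max(metrics$cophenetic) - cophenetic_tol
  cand <- which(tied)
  best <- cand[order(-metrics$mean_silhouette[cand],
                     metrics$k[cand])][1L]
  k_sel <- k_range[best]

  fit <- nmf_factorize(beta_matrix(x), k_sel, seed = seed,
                       max_iter = max_iter, tol = tol)
  assignments <- per_k[[as.character(k_sel)]]$assignments

  ## report in the caller's original sample order
  back <- match(rownames(beta), ids)
  out <- list(k_selected = k_sel,
              assignments = assignments[back],
              per_k = per_k,
              metrics = metrics,
              basis = fit$basis,
              coef = fit$coef[, back, drop = FALSE])
  class(out) <- "consensus_result"
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k_selected = %d\n", x$k_selected))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Per-sample silhouette widths
#'
#' Standard silhouette \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))} where
#' `a(i)` is the mean dissimilarity of sample `i` to its own cluster and
#' `b(i)` the smallest mean dissimilarity to another cluster.
#'
#' @param distance a `dist` object or square dissimilarity matrix.
#' @param assignments cluster index per sample (>= 2 distinct clusters).
#' @return numeric vector of silhouette widths in \eqn{[-1, 1]}.
#' @export
silhouette_widths <- function(distance, assignments) {
  dmat <- as.matrix(distance)
  assignments <- as.integer(factor(assignments))
  if (length(unique(assignments)) < 2L)
    stop("silhouette requires at least two clusters")
  if (length(assignments) != nrow(dmat))
    stop("assignments do not match the dissimilarity matrix")
  si <- cluster::silhouette(assignments, dmatrix = dmat)
  widths <- if (is.matrix(si)) si[, "sil_width"] else rep(0, length(assignments))
  as.numeric(widths)
}

#' Match predicted cluster labels to reference labels
#'
#' Finds the one-to-one relabelling of predicted clusters that maximises
#' agreement with the reference labels, by solving the assignment problem
#' on the confusion matrix (Hungarian algorithm). Unequal label
#' cardinalities are handled by padding with empty classes.
#'
#' @param predicted,truth equal-length label vectors.
#' @return list with `map` (named character vector: predicted label ->
#'   matched truth label) and `agreement` (fraction of samples matching
#'   after relabelling).
#' @export
match_labels <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have equal length")
  pl <- sort(unique(as.character(predicted)))
  tl <- sort(unique(as.character(truth)))
  k <- max(length(pl), length(tl))
  conf <- matrix(0, k, k)
  conf[seq_along(pl), seq_along(tl)] <-
    as.matrix(table(factor(predicted, pl), factor(truth, tl)))
  assign_idx <- solve_assignment(max(conf) - conf)   # minimise cost
  map <- setNames(rep(NA_character_, length(pl)), pl)
  for (i in seq_along(pl)) {
    j <- assign_idx[i]
    if (j <= length(tl)) map[pl[i]] <- tl[j]
  }
  matched <- map[as.character(predicted)]
  list(map = map, agreement = mean(!is.na(matched) & matched == truth))
}

## Hungarian algorithm (Jonker-style augmenting path with potentials) for
## the square assignment problem; returns the column matched to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)                  # p[j] = row matched to column j
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                            # 1-indexed column 0 sentinel
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match_col <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) match_col[p[j]] <- j - 1L
  match_col
}

#' Principal component visualisation of a beta matrix
#'
#' Plotting helper: projects samples onto the first two principal
#' components of the (median-imputed) beta matrix, coloured by group.
#' Purely descriptive; no statistics are attached.
#'
#' @param beta a [beta_matrix()].
#' @param groups optional group per sample.
#' @param ... passed to [plot()].
#' @return the `prcomp` fit, invisibly.
#' @export
plot_pca <- function(beta, groups = NULL, ...) {
  x <- impute_locus_median(beta)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  plot(pc$x[, 1L], pc$x[, 2L], col = col, pch = 19,
       xlab = "PC1", ylab = "PC2", ...)
  invisible(pc)
}
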