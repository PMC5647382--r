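#' Select signature candidate loci per subgroup
#'
#' Takes per-subgroup [moderated_t_stats()] tables and keeps the
#' `per_group_k` loci with the largest absolute moderated t in each
#' one-vs-rest contrast, after removing loci rejected by the assay design
#' filter (in practice: amenability to primer design and multiplex
#' bisulfite PCR; the default filter passes everything and the interface
#' is pluggable). Per-subgroup lists are pooled with deduplication.
#'
#' @param stats_list named list (one element per subgroup) of `locus_stats`
#'   data.frames as returned by [moderated_t_stats()].
#' @param per_group_k candidates kept per subgroup.
#' @param design_filter `NULL` (pass-all) or a vectorised predicate
#'   `function(locus_id) -> logical`; rejected loci are recorded and the
#'   next-ranked eligible loci take their place.
#' @return a list of class `candidate_set`: `per_group` (named list of
#'   ranked locus ids), `pooled` (unique locus ids), `rejected`
#'   (data.frame of filtered loci with reasons).
#' @export
select_candidates <- function(stats_list, per_group_k = 50L,
                              design_filter = NULL) {
  if (is.null(names(stats_list)) || any(names(stats_list) == ""))
    stop("'stats_list' must be a named per-subgroup list")
  per_group <- list()
  rejected <- data.frame(locus_id = character(), subgroup = character(),
                         reason = character(), stringsAsFactors = FALSE)
  for (g in names(stats_list)) {
    st <- stats_list[[g]]
    ## locus_stats are already sorted by |t| descending, ties by id
    ids <- st$locus_id
    if (!is.null(design_filter)) {
      pass <- design_filter(ids)
      if (any(!pass))
        rejected <- rbind(rejected,
                          data.frame(locus_id = ids[!pass], subgroup = g,
                                     reason = "design_filter",
                                     stringsAsFactors = FALSE))
      ids <- ids[pass]
    }
    if (length(ids) < per_group_k)
      stop(sprintf("subgroup '%s': only %d eligible loci (< %d)",
                   g, length(ids), per_group_k))
    per_group[[g]] <- ids[seq_len(per_group_k)]
  }
  out <- list(per_group = per_group,
              pooled = unique(unlist(per_group, use.names = FALSE)),
              rejected = rejected)
  class(out) <- "candidate_set"
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d pooled loci from %d contrasts (%d rejected)\n",
              length(x$pooled), length(x$per_group), nrow(x$rejected)))
  invisible(x)
}

## default two-stage subgrouping scheme used throughout: first separate
## WNT vs SHH vs the merged Grp3/Grp4 branch, then split Grp3 vs Grp4.
default_scheme <- function(classes) {
  if (all(c("Grp3", "Grp4") %in% classes)) {
    merged <- setNames(classes, classes)
    merged[c("Grp3", "Grp4")] <- "Grp3/Grp4"
    list(stage1 = merged, stage2 = c("Grp3", "Grp4"))
  } else {
    list(stage1 = setNames(classes, classes), stage2 = NULL)
  }
}

#' Rank candidate loci by cross-validated classifier fusion
#'
#' Ranks loci by fusing the per-locus importances of four base learners --
#' linear support vector machine (mean absolute discriminant weight over
#' class pairs), single-hidden-layer neural network (held-out permutation
#' importance), CART decision tree (Gini impurity importance) and a naive
#' Bayes network over beta discretised into three methylation states
#' (unmethylated < 0.25, hemimethylated, methylated > 0.75; scored by
#' class-locus mutual information). Importances are averaged over
#' stratified cross-validation folds, converted to ranks per learner, and
#' fused as the arithmetic mean of ranks.
#'
#' Ranking runs in two stages mirroring the subgrouping hierarchy (three
#' classes: WNT, SHH and merged Grp3/Grp4; then two classes: Grp3 vs
#' Grp4); a locus's overall fused rank is its best stage rank, re-ranked
#' with ties broken by mean normalised importance and then locus id.
#' Loci are processed in identifier order, so the result is invariant to
#' the column order of the input matrix.
#'
#' @param beta a [beta_matrix()] restricted to candidate loci (no missing
#'   values).
#' @param labels subgroup label per sample.
#' @param scheme `NULL` for the default hierarchy, or a list like the one
#'   built by the default: `stage1` a named class-merge map, `stage2` a
#'   pair of classes to separate (or `NULL`).
#' @param n_folds stratified cross-validation folds.
#' @param seed integer seed (fold assignment, learner initialisation).
#' @return a list of class `fusion_ranking`: `table` (per-locus per-stage
#'   per-learner ranks, stage fused ranks, overall `fused_rank`),
#'   `ranked_loci` (locus ids by fused rank) and `scheme_descriptor`.
#' @export
fusion_rank <- function(beta, labels, scheme = NULL, n_folds = 10L,
                        seed = 1L) {
  labels <- as.character(labels)
  if (anyNA(beta)) stop("missing values present; impute before ranking")
  loci <- sort(colnames(beta))
  x <- unclass_beta(beta)[, loci, drop = FALSE]
  classes <- sort(unique(labels))
  if (is.null(scheme)) scheme <- default_scheme(classes)

  stages <- list()
  s1_labels <- unname(scheme$stage1[labels])
  stages$stage1 <- list(x = x, y = s1_labels)
  if (!is.null(scheme$stage2)) {
    keep <- labels %in% scheme$stage2
    stages$stage2 <- list(x = x[keep, , drop = FALSE], y = labels[keep])
  }

  imp_tables <- list()
  for (sn in names(stages)) {
    st <- stages[[sn]]
    imp_tables[[sn]] <- stage_importances(st$x, st$y, n_folds = n_folds,
                                          seed = seed)
  }

  tab <- data.frame(locus_id = loci, stringsAsFactors = FALSE)
  stage_fused <- matrix(NA_real_, length(loci), length(imp_tables),
                        dimnames = list(loci, names(imp_tables)))
  mean_imp <- matrix(0, length(loci), length(imp_tables))
  for (si in seq_along(imp_tables)) {
    sn <- names(imp_tables)[si]
    imp <- imp_tables[[si]]                      # loci x learners
    ranks <- apply(imp, 2L, function(v)
      rank(-v, ties.method = "first"))           # loci sorted by id already
    colnames(ranks) <- paste(sn, colnames(imp), sep = ".")
    tab <- cbind(tab, ranks)
    stage_fused[, si] <- rowMeans(ranks)
    tab[[paste0(sn, ".fused")]] <- stage_fused[, si]
    ## normalised importances for tie-breaking
    rng <- apply(imp, 2L, function(v) {
      s <- max(v) - min(v)
      if (s > 0) (v - min(v)) / s else rep(0, length(v))
    })
    mean_imp[, si] <- rowMeans(rng)
  }
  best_stage <- apply(stage_fused, 1L, min)
  tiebreak <- apply(mean_imp, 1L, max)
  ord <- order(best_stage, -tiebreak, loci)
  fused_rank <- integer(length(loci))
  fused_rank[ord] <- seq_along(loci)
  tab$fused_rank <- fused_rank

  out <- list(table = tab,
              ranked_loci = loci[ord],
              scheme_descriptor = sprintf(
                "%d-fold stratified CV; stages: %s",
                n_folds, paste(names(stages), collapse = " -> ")))
  class(out) <- "fusion_ranking"
  out
}

#' @export
print.fusion_ranking <- function(x, ...) {
  cat(sprintf("fusion_ranking: %d loci (%s)\n",
              nrow(x$table), x$scheme_descriptor))
  invisible(x)
}

## stratified fold assignment: samples of each class dealt round-robin
stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

## per-locus importances for one stage, averaged over CV folds;
## returns a loci x learner matrix (columns svm, ann, dt, bn)
stage_importances <- function(x, y, n_folds = 10L, seed = 1L) {
  y <- factor(y)
  if (min(table(y)) < n_folds)
    n_folds <- max(2L, min(table(y)))
  fold <- stratified_folds(as.character(y), n_folds, seed)
  p <- ncol(x)
  acc <- matrix(0, p, 4L, dimnames = list(colnames(x),
                                          c("svm", "ann", "dt", "bn")))
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < nlevels(y))
      stop("a cross-validation fold lost a class; reduce n_folds")
    xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    xte <- x[te, , drop = FALSE]; yte <- y[te]
    acc[, "svm"] <- acc[, "svm"] + svm_weight_importance(xtr, ytr)
    acc[, "ann"] <- acc[, "ann"] + ann_perm_importance(xtr, ytr, xte, yte,
                                                       seed = seed + f)
    acc[, "dt"] <- acc[, "dt"] + dt_importance(xtr, ytr)
    acc[, "bn"] <- acc[, "bn"] + nb_mi_importance(xtr, ytr)
  }
  acc / n_folds
}

## mean |w| over one-vs-one linear SVM discriminants
svm_weight_importance <- function(x, y) {
  cls <- levels(y)
  pairs <- utils::combn(cls, 2L, simplify = FALSE)
  w_abs <- matrix(0, ncol(x), length(pairs))
  for (i in seq_along(pairs)) {
    sel <- y %in% pairs[[i]]
    fit <- e1071::svm(x[sel, , drop = FALSE], droplevels(y[sel]),
                      kernel = "linear", scale = FALSE, cost = 1)
    w <- crossprod(fit$coefs, fit$SV)
    w_abs[, i] <- abs(as.numeric(w))
  }
  rowMeans(w_abs)
}

## held-out accuracy drop when each locus is permuted
ann_perm_importance <- function(xtr, ytr, xte, yte, size = 3L, seed = 1L) {
  set.seed(seed)
  fit <- nnet::nnet(xtr, nnet::class.ind(ytr), size = size, decay = 0.01,
                    maxit = 120, softmax = TRUE, trace = FALSE,
                    MaxNWts = 50000)
  pred_cls <- function(m) levels(ytr)[apply(predict(fit, m), 1L, which.max)]
  base <- mean(pred_cls(xte) == as.character(yte))
  imp <- numeric(ncol(xtr))
  perm <- sample(nrow(xte))
  for (j in seq_len(ncol(xtr))) {
    xp <- xte
    xp[, j] <- xp[perm, j]
    imp[j] <- base - mean(pred_cls(xp) == as.character(yte))
  }
  imp
}

## CART Gini importance; loci unused by the tree score 0
dt_importance <- function(x, y) {
  df <- data.frame(x, check.names = FALSE)
  df$.class <- y
  fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = 0.001,
                                                     xval = 0L))
  imp <- setNames(numeric(ncol(x)), colnames(x))
  vi <- fit$variable.importance
  if (!is.null(vi)) imp[names(vi)] <- vi
  unname(imp)
}

## naive Bayes relevance: mutual information between the three-state
## discretised locus (unmethylated < 0.25, hemi, methylated > 0.75) and
## the class
nb_mi_importance <- function(x, y) {
  disc <- matrix(cut(x, breaks = c(-Inf, 0.25, 0.75, Inf),
                     labels = FALSE), nrow(x), ncol(x))
  n <- nrow(x)
  py <- table(y) / n
  hy <- -sum(py * log(py))
  imp <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    tab <- table(disc[, j], y) / n
    px <- rowSums(tab)
    cond <- 0
    for (b in seq_along(px)) {
      if (px[b] > 0) {
        pc <- tab[b, ] / px[b]
        pc <- pc[pc > 0]
        cond <- cond + px[b] * (-sum(pc * log(pc)))
      }
    }
    imp[j] <- hy - cond
  }
  imp
}

#' Optimise signature redundancy under random locus masking
#'
#' Starting from the `target_size` top-ranked loci, repeatedly evaluates
#' candidate panels by their mean stratified cross-validated accuracy when
#' up to `max_remove` randomly chosen panel loci are masked (masked values
#' are replaced by training-fold means before prediction, emulating
#' imputation at assay time). Each round tries swapping every panel locus
#' for the next-ranked alternative and keeps the best swap; the search
#' stops when no swap improves the masked accuracy, returning a panel of
#' exactly `target_size` loci whose classification survives locus dropout.
#'
#' With `n_iter = 0` the optimisation is disabled and the top
#' `target_size` loci by fused rank are returned unchanged.
#'
#' @param ranking a [fusion_rank()] result.
#' @param beta candidate-loci [beta_matrix()] (no missing values).
#' @param labels subgroup label per sample.
#' @param target_size panel size.
#' @param max_remove maximum number of loci masked per evaluation draw.
#' @param n_iter random masks per panel evaluation.
#' @param n_folds cross-validation folds for the masked-accuracy score.
#' @param max_rounds cap on greedy swap rounds.
#' @param seed integer seed.
#' @param candidates optional [select_candidates()] result used to annotate
#'   each signature locus with its contributing contrast.
#' @return a [signature_definition()] of exactly `target_size` loci, with
#'   attributes `robustness` (final masked CV accuracy) and `history`
#'   (accepted swaps).
#' @export
redundancy_optimize <- function(ranking, beta, labels, target_size = 17L,
                                max_remove = 6L, n_iter = 50L,
                                n_folds = 10L, max_rounds = 5L, seed = 1L,
                                candidates = NULL) {
  ranked <- ranking$ranked_loci
  if (length(ranked) < target_size + max_remove)
    stop("not enough ranked candidates for the requested panel size")
  if (anyNA(beta)) stop("missing values present; impute first")
  x <- unclass_beta(beta)
  labels <- factor(as.character(labels))

  sig <- ranked[seq_len(target_size)]
  alternatives <- ranked[-seq_len(target_size)]
  history <- data.frame(round = integer(), removed = character(),
                        added = character(), score = numeric(),
                        stringsAsFactors = FALSE)

  if (n_iter > 0L) {
    fold <- stratified_folds(as.character(labels), n_folds, seed)
    score_panel <- function(panel) {
      masked_cv_accuracy(x[, panel, drop = FALSE], labels, fold,
                         max_remove = max_remove, n_iter = n_iter,
                         seed = seed)
    }
    current <- score_panel(sig)
    for (round in seq_len(max_rounds)) {
      if (!length(alternatives)) break
      alt <- alternatives[1L]
      best_score <- current; best_i <- 0L
      for (i in seq_along(sig)) {
        trial <- sig
        trial[i] <- alt
        s <- score_panel(trial)
        if (s > best_score + 1e-12) { best_score <- s; best_i <- i }
      }
      if (best_i == 0L) break
      history <- rbind(history,
                       data.frame(round = round, removed = sig[best_i],
                                  added = alt, score = best_score,
                                  stringsAsFactors = FALSE))
      sig[best_i] <- alt
      alternatives <- alternatives[-1L]
      current <- best_score
    }
    robustness <- current
  } else {
    robustness <- NA_real_
  }

  contrast <- rep(NA_character_, length(sig))
  if (!is.null(candidates)) {
    for (g in names(candidates$per_group))
      contrast[sig %in% candidates$per_group[[g]]] <- g
  }
  out <- signature_definition(sig, contrast = contrast,
                              plex = rep_len(1:3, length(sig)))
  attr(out, "robustness") <- robustness
  attr(out, "history") <- history
  out
}

## mean CV accuracy of a linear SVM on the panel when each test sample has
## a random subset of 0..max_remove panel loci masked (mean-imputed);
## mask patterns are drawn from a fixed-seed local RNG so that competing
## panels are scored on identical mask draws (common random numbers)
masked_cv_accuracy <- function(xp, y, fold, max_remove, n_iter, seed) {
  rng <- local_rng(seed + 7L)
  total <- 0; n_eval <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fit <- e1071::svm(xp[tr, , drop = FALSE], droplevels(y[tr]),
                      kernel = "linear", scale = FALSE, cost = 1)
    mu <- colMeans(xp[tr, , drop = FALSE])
    xte <- xp[!tr, , drop = FALSE]
    yte <- as.character(y[!tr])
    for (m in seq_len(n_iter)) {
      n_rm <- rng$int(max_remove + 1L) - 1L
      xm <- xte
      if (n_rm > 0L) {
        rm_idx <- rng$pick(ncol(xp), n_rm)
        xm[, rm_idx] <- rep(mu[rm_idx], each = nrow(xm))
      }
      total <- total + mean(as.character(predict(fit, xm)) == yte)
      n_eval <- n_eval + 1L
    }
  }
  total / n_eval
}

## tiny deterministic generator (linear congruential) independent of the
## global RNG stream, used where common random numbers are needed
local_rng <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  nxt <- function() {
    state <<- (state * 48271) %% 2147483647
    state / 2147483647
  }
  list(int = function(n) floor(nxt() * n) + 1L,
       pick = function(n, k) {
         idx <- integer(0)
         while (length(idx) < k) idx <- unique(c(idx, floor(nxt() * n) + 1L))
         idx[seq_len(k)]
       })
}

#' Run the full signature design pipeline
#'
#' Convenience wrapper: per-subgroup moderated-t candidate selection
#' ([moderated_t_stats()], [select_candidates()]), cross-validated
#' classifier-fusion ranking ([fusion_rank()]) and redundancy optimisation
#' under random locus masking ([redundancy_optimize()]).
#'
#' @param beta training [beta_matrix()].
#' @param labels subgroup label per sample.
#' @param per_group_k candidates per subgroup contrast.
#' @param target_size final panel size.
#' @param design_filter optional locus predicate (see
#'   [select_candidates()]).
#' @param n_folds,max_remove,n_iter,seed passed to the component stages.
#' @return the [signature_definition()]; the intermediate `candidate_set`
#'   and `fusion_ranking` are attached as attributes `candidates` and
#'   `ranking`.
#' @export
design_signature <- function(beta, labels, per_group_k = 50L,
                             target_size = 17L, design_filter = NULL,
                             n_folds = 10L, max_remove = 6L, n_iter = 50L,
                             seed = 1L) {
  x <- beta_matrix(impute_locus_median(beta))
  groups <- sort(unique(as.character(labels)))
  stats_list <- lapply(setNames(groups, groups), function(g)
    moderated_t_stats(x, labels, g))
  cand <- select_candidates(stats_list, per_group_k = per_group_k,
                            design_filter = design_filter)
  xc <- beta_matrix(unclass_beta(x)[, cand$pooled, drop = FALSE])
  ranking <- fusion_rank(xc, labels, n_folds = n_folds, seed = seed)
  sig <- redundancy_optimize(ranking, xc, labels,
                             target_size = target_size,
                             max_remove = max_remove, n_iter = n_iter,
                             n_folds = n_folds, seed = seed,
                             candidates = cand)
  attr(sig, "candidates") <- cand
  attr(sig, "ranking") <- ranking
  sig
}
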