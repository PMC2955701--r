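# Feature selection and the two-stage cost-sensitive RBF-SVM.
#
# Training protocol per stage: mRMR feature ranking (per-CV-fold with Borda
# aggregation by default), sequential forward search over rank-list prefixes
# scored by cross-validated F_beta at fixed moderate SVM parameters, then a
# 2-D grid search over (C, gamma) on the selected subset with class weights
# in the cost ratio j = n_neg/n_pos. The SVM itself is a weighted C-SVC
# solved by SMO (see src/smo.cpp).

#' F_beta score
#'
#' \eqn{F_\beta = (1+\beta^2) p r / (\beta^2 p + r)}; returns 0 when the
#' denominator is 0. At beta = 1 this is the harmonic mean of precision and
#' sensitivity.
#'
#' @param p precision in \[0, 1\].
#' @param r sensitivity (recall) in \[0, 1\].
#' @param beta non-negative weight (default 1).
#' @return the F_beta score.
#' @export
f_beta <- function(p, r, beta = 1) {
  stopifnot(beta >= 0, p >= 0, p <= 1, r >= 0, r <= 1)
  den <- beta^2 * p + r
  if (den == 0) return(0)
  (1 + beta^2) * p * r / den
}

# discretize a feature column for MI estimation: integer-valued columns with
# few distinct values are categorical; continuous columns get 3 states cut
# at mean +/- sd
.mi_discretize <- function(x) {
  ux <- unique(x)
  if (length(ux) <= 1) return(rep(1L, length(x)))
  if (all(x == round(x)) && length(ux) <= 16)
    return(match(x, sort(ux)))
  mu <- mean(x); s <- stats::sd(x)
  if (s == 0) return(rep(1L, length(x)))
  findInterval(x, c(mu - s, mu + s)) + 1L
}

#' Mutual information between two variables (bits)
#'
#' Plug-in estimate on discretized data: continuous columns are cut into 3
#' states at mean +/- one standard deviation, integer-coded columns with at
#' most 16 distinct values are used as-is.
#'
#' @param x,y equal-length numeric vectors.
#' @return mutual information estimate in bits (>= 0; 0 for a constant
#'   vector).
#' @export
mutual_information <- function(x, y) {
  stopifnot(length(x) == length(y))
  cx <- .mi_discretize(x); cy <- .mi_discretize(y)
  nx <- max(cx); ny <- max(cy)
  n <- length(x)
  joint <- tabulate(cx + nx * (cy - 1L), nx * ny) / n
  px <- tabulate(cx, nx) / n
  py <- tabulate(cy, ny) / n
  pj <- matrix(joint, nx, ny)
  mi <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (pj[i, j] > 0)
      mi <- mi + pj[i, j] * log2(pj[i, j] / (px[i] * py[j]))
  }
  max(mi, 0)
}

# full pairwise MI matrix among feature columns (discretized once)
.mi_matrix <- function(X) {
  d <- ncol(X)
  cols <- lapply(seq_len(d), function(j) .mi_discretize(X[, j]))
  n <- nrow(X)
  M <- matrix(0, d, d)
  for (i in seq_len(d)) {
    ci <- cols[[i]]; ni <- max(ci)
    pi_ <- tabulate(ci, ni) / n
    for (j in i:d) {
      cj <- cols[[j]]; nj <- max(cj)
      joint <- tabulate(ci + ni * (cj - 1L), ni * nj) / n
      pj_ <- tabulate(cj, nj) / n
      pm <- matrix(joint, ni, nj)
      mi <- 0
      for (a in seq_len(ni)) for (b in seq_len(nj)) {
        if (pm[a, b] > 0)
          mi <- mi + pm[a, b] * log2(pm[a, b] / (pi_[a] * pj_[b]))
      }
      M[i, j] <- M[j, i] <- max(mi, 0)
    }
  }
  M
}

#' mRMR feature ranking
#'
#' Greedy minimal-redundancy maximal-relevance ranking: the first feature
#' maximizes I(x_i; c); each subsequent pick maximizes the set objective
#' Phi = D - R, with D the mean feature-label MI over the selected set and R
#' the mean pairwise MI over all ordered feature pairs (diagonal included,
#' per the defining sums). Ties break to the lowest column index.
#'
#' @param X numeric feature matrix (>= 2 columns).
#' @param labels class labels (numeric/logical/factor).
#' @return integer vector: a permutation of 1..ncol(X), best first.
#' @export
mrmr_rank <- function(X, labels) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (d < 2) stop("mrmr_rank needs at least 2 features")
  y <- as.numeric(as.factor(labels))
  rel <- vapply(seq_len(d), function(j) mutual_information(X[, j], y), 0)
  M <- .mi_matrix(X)
  sel <- integer(0)
  avail <- seq_len(d)
  relsum <- 0; redsum <- 0
  for (step in seq_len(d)) {
    k <- length(sel)
    phi <- vapply(avail, function(j) {
      D <- (relsum + rel[j]) / (k + 1)
      R <- (redsum + 2 * sum(M[j, sel]) + M[j, j]) / (k + 1)^2
      D - R
    }, 0)
    pick <- avail[which.max(phi)]
    relsum <- relsum + rel[pick]
    redsum <- redsum + 2 * sum(M[pick, sel]) + M[pick, pick]
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  sel
}

#' Training configuration for one SVM stage
#'
#' @param c_grid penalty-constant grid (default powers of 4 spanning
#'   2^-5..2^15).
#' @param gamma_grid RBF width grid (default powers of 4 spanning
#'   2^-15..2^3).
#' @param folds cross-validation folds (default 5, stratified).
#' @param beta F score weight (default 1).
#' @param seed RNG seed controlling fold assignment and any subsampling.
#' @param sfs_max cap on rank-list prefixes tried in forward search.
#' @param sfs_C,sfs_gamma fixed SVM parameters used while searching features
#'   (`NULL` gamma means 1/n_features).
#' @param mrmr_mode "per_fold" (rank in each CV fold, Borda-aggregate) or
#'   "global".
#' @param cost_ratio class-weight ratio j (`NULL` = n_neg/n_pos).
#' @param max_neg_sites cap on negative site examples (subsampled, seeded).
#' @return list of class `TrainConfig`.
#' @export
train_config <- function(c_grid = 2^seq(-5, 15, 2),
                         gamma_grid = 2^seq(-15, 3, 2),
                         folds = 5L, beta = 1, seed = 42L,
                         sfs_max = 30L, sfs_C = 1, sfs_gamma = NULL,
                         mrmr_mode = c("per_fold", "global"),
                         cost_ratio = NULL, max_neg_sites = 600L) {
  stopifnot(length(c_grid) > 0, length(gamma_grid) > 0, folds >= 2)
  structure(list(c_grid = c_grid, gamma_grid = gamma_grid,
                 folds = as.integer(folds), beta = beta,
                 seed = as.integer(seed), sfs_max = as.integer(sfs_max),
                 sfs_C = sfs_C, sfs_gamma = sfs_gamma,
                 mrmr_mode = match.arg(mrmr_mode),
                 cost_ratio = cost_ratio,
                 max_neg_sites = as.integer(max_neg_sites)),
            class = "TrainConfig")
}

# stratified fold assignment, deterministic given seed
.make_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.scale_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

# fit a weighted C-SVC; y is 0/1
.svm_fit <- function(X, y, C, gamma, cost_ratio) {
  yi <- ifelse(y > 0, 1L, -1L)
  Cvec <- ifelse(yi > 0, C * cost_ratio, C)
  fit <- svm_smo_fit(as.matrix(X), yi, Cvec, gamma)
  list(X = as.matrix(X), y = yi, alpha = fit$alpha, b = fit$b, gamma = gamma)
}

.svm_decision <- function(fit, Xnew) {
  svm_decision_cpp(fit$X, fit$y, fit$alpha, fit$b, fit$gamma,
                   as.matrix(Xnew))
}

# mean CV F_beta of an SVM at fixed parameters over precomputed folds
.cv_fscore <- function(X, y, C, gamma, cost_ratio, fold, beta) {
  ks <- sort(unique(fold))
  fs <- vapply(ks, function(k) {
    tr <- fold != k; te <- !tr
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- .svm_fit(X[tr, , drop = FALSE], y[tr], C, gamma, cost_ratio)
    pred <- .svm_decision(fit, X[te, , drop = FALSE]) > 0
    tp <- sum(pred & y[te] > 0)
    p <- if (sum(pred) > 0) tp / sum(pred) else 0
    r <- if (sum(y[te] > 0) > 0) tp / sum(y[te] > 0) else 0
    f_beta(p, r, beta)
  }, 0)
  mean(fs, na.rm = TRUE)
}

#' Sequential forward search over a feature rank list
#'
#' Features are added in rank order; the prefix maximizing cross-validated
#' F_beta (SVM at the configuration's fixed `sfs_C`/`sfs_gamma`) is
#' retained; ties go to the smaller subset.
#'
#' @param ranked integer rank list from [mrmr_rank()].
#' @param X feature matrix (unscaled; scaled internally).
#' @param y 0/1 labels.
#' @param config a `TrainConfig`.
#' @return list with `features` (selected column indices, in rank order) and
#'   `cv_f` (its cross-validated F score).
#' @export
sequential_forward_search <- function(ranked, X, y, config = train_config()) {
  X <- as.matrix(X)
  sc <- .scale_fit(X)
  Xs <- .scale_apply(X, sc)
  j <- config$cost_ratio
  if (is.null(j)) j <- sum(y == 0) / sum(y > 0)
  fold <- .make_folds(y, config$folds, config$seed)
  kmax <- min(config$sfs_max, length(ranked))
  scores <- vapply(seq_len(kmax), function(k) {
    gamma <- if (is.null(config$sfs_gamma)) 1 / k else config$sfs_gamma
    .cv_fscore(Xs[, ranked[1:k], drop = FALSE], y, config$sfs_C, gamma, j,
               fold, config$beta)
  }, 0)
  best <- which.max(scores)          # first max = smallest subset on ties
  list(features = ranked[seq_len(best)], cv_f = scores[best])
}

#' Grid-search and train one SVM stage
#'
#' 2-D grid search over (C, gamma) maximizing mean cross-validated F_beta
#' with class weights in ratio j = n_neg/n_pos, then a final refit on all
#' data.
#'
#' @param X feature matrix (rows = examples).
#' @param y 0/1 labels (both classes required).
#' @param config a `TrainConfig`.
#' @param stage "site" or "utr".
#' @param feature_names names of the columns of `X` (stored in the model).
#' @return object of class `StageModel`.
#' @export
grid_search_train <- function(X, y, config = train_config(),
                              stage = c("site", "utr"),
                              feature_names = colnames(X)) {
  stage <- match.arg(stage)
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("both classes required for training")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(X)))
  sc <- .scale_fit(X)
  Xs <- .scale_apply(X, sc)
  j <- config$cost_ratio
  if (is.null(j)) j <- sum(y == 0) / sum(y > 0)
  fold <- .make_folds(y, config$folds, config$seed)
  best <- list(f = -Inf, C = NA, gamma = NA)
  for (C in config$c_grid) for (gamma in config$gamma_grid) {
    f <- .cv_fscore(Xs, y, C, gamma, j, fold, config$beta)
    if (f > best$f) best <- list(f = f, C = C, gamma = gamma)
  }
  fit <- .svm_fit(Xs, y, best$C, best$gamma, j)
  structure(list(stage = stage, feature_names = feature_names,
                 schema = schema_hash(feature_names),
                 center = sc$center, scale = sc$scale,
                 fit = fit, C = best$C, gamma = best$gamma,
                 cost_ratio = j, cv_f = best$f),
            class = "StageModel")
}

#' @export
print.StageModel <- function(x, ...) {
  cat("<StageModel ", x$stage, "> ", length(x$feature_names),
      " feature(s), C=", x$C, " gamma=", signif(x$gamma, 3),
      " j=", round(x$cost_ratio, 2), " cv_F=", round(x$cv_f, 3), "\n",
      sep = "")
  invisible(x)
}

#' Decision scores of a stage model
#'
#' @param model a `StageModel`.
#' @param X feature matrix whose columns match the model's feature names.
#' @return numeric decision scores (positive = predicted positive).
#' @export
predict_stage <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    missing_cols <- setdiff(model$feature_names, colnames(X))
    if (length(missing_cols))
      stop("feature schema mismatch; missing: ",
           paste(utils::head(missing_cols, 5), collapse = ", "))
    X <- X[, model$feature_names, drop = FALSE]
  } else if (ncol(X) != length(model$feature_names)) {
    stop("feature schema mismatch: expected ", length(model$feature_names),
         " columns")
  }
  .svm_decision(model$fit, .scale_apply(X, list(center = model$center,
                                                scale = model$scale)))
}

# rank features by mRMR, either once globally or per CV fold with Borda
# aggregation (lower summed position = better)
.rank_features <- function(X, y, config) {
  if (config$mrmr_mode == "global") return(mrmr_rank(X, y))
  fold <- .make_folds(y, config$folds, config$seed)
  d <- ncol(X)
  pos_sum <- numeric(d)
  for (k in sort(unique(fold))) {
    r <- mrmr_rank(X[fold != k, , drop = FALSE], y[fold != k])
    pos_sum[r] <- pos_sum[r] + seq_len(d)
  }
  order(pos_sum)
}

#' Train one stage end-to-end (rank, select, grid search)
#'
#' @param X feature matrix with named columns.
#' @param y 0/1 labels.
#' @param config a `TrainConfig`.
#' @param stage "site" or "utr".
#' @return a `StageModel` restricted to the selected features.
#' @export
train_stage <- function(X, y, config = train_config(),
                        stage = c("site", "utr")) {
  stage <- match.arg(stage)
  X <- as.matrix(X)
  ranked <- .rank_features(X, y, config)
  sel <- sequential_forward_search(ranked, X, y, config)
  message(stage, "-SVM: ", length(sel$features), " feature(s) selected, ",
          "SFS cv_F=", round(sel$cv_f, 3))
  grid_search_train(X[, sel$features, drop = FALSE], y, config, stage,
                    feature_names = colnames(X)[sel$features])
}

#' Predict and rank miRNA targets
#'
#' Runs the full per-UTR pipeline (site scan, duplex fold, site features,
#' site scores, UTR features, UTR score) and returns UTRs ranked by
#' descending UTR-SVM score. UTRs with no candidate site get the
#' [score_floor()] sentinel and sort last; ties break by utr_id.
#'
#' @param mirna a `MirnaSeq`.
#' @param utrs named list of `UtrSeq`.
#' @param site_model,utr_model trained `StageModel`s.
#' @param params energy parameters.
#' @param window_pad accessibility pad.
#' @return data.frame (utr_id, score, n_sites, n_positive_sites), ranked.
#' @export
predict_targets <- function(mirna, utrs, site_model, utr_model,
                            params = default_energy_params(),
                            window_pad = 70) {
  rows <- lapply(utrs, function(u) {
    sites <- scan_sites(mirna, u)
    if (!length(sites))
      return(data.frame(utr_id = u$id, score = score_floor(), n_sites = 0L,
                        n_positive_sites = 0L, stringsAsFactors = FALSE))
    Xs <- t(vapply(sites, function(s)
      extract_site_features(s, u, mirna, params = params,
                            window_pad = window_pad),
      numeric(113)))
    s_scores <- predict_stage(site_model, Xs)
    uf <- extract_utr_features(u, sites, s_scores)
    u_score <- predict_stage(utr_model, matrix(uf, 1,
                                               dimnames = list(NULL, names(uf))))
    data.frame(utr_id = u$id, score = u_score, n_sites = length(sites),
               n_positive_sites = sum(s_scores > 0), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$utr_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
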