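# Genotype discrimination by linear discriminant analysis over behavioral
# feature sets. Features are z-scored per column on the training data;
# the pooled within-class covariance is shrunk toward a scaled identity
# just enough to be well conditioned, which keeps the many-feature /
# few-animal regime (26 movement features, ~15 animals per class) stable.
# Sexes are analyzed separately throughout.

#' Build a per-animal feature table
#'
#' Feature sets: `movements` (13 time fractions + 13 bout frequencies),
#' `grooming` (fraction + frequency), `distance` (total mm), `position`
#' (center and perimeter time fractions under the given division, default
#' traditional), `clusters` (5 fractions + 5 frequencies).
#'
#' @param cohort A [cohort()].
#' @param feature_set One of `"movements"`, `"grooming"`, `"distance"`,
#'   `"position"`, `"clusters"`.
#' @param division A [zone_division()] for the position set; default
#'   traditional.
#' @param sex Optional sex filter (`"M"`/`"F"`); sexes are modeled
#'   separately, so discrimination runs usually pass one.
#' @param map Cluster map for the clusters set.
#' @return Object of class `feature_table`: data.frame with `animal_id`,
#'   `genotype`, `sex` and the feature columns; attribute `feature_set`.
#' @export
build_features <- function(cohort,
                           feature_set = c("movements", "grooming",
                                           "distance", "position", "clusters"),
                           division = zone_division("traditional"),
                           sex = NULL, map = cluster_map()) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(cohort, "cohort"))
  subs <- cohort$subjects
  if (!is.null(sex)) subs <- subs[subs$sex %in% sex, , drop = FALSE]
  if (!nrow(subs)) stop("no animals match the sex filter", call. = FALSE)
  feat_row <- function(id) {
    e <- cohort$ethograms[[id]]; t <- cohort$trajectories[[id]]
    switch(feature_set,
      movements = {
        tb <- time_budget(e)
        c(stats::setNames(tb$fractions, paste0("frac_", names(tb$fractions))),
          stats::setNames(tb$frequencies,
                          paste0("freq_", names(tb$frequencies))))
      },
      grooming = {
        tb <- time_budget(e)
        c(frac_grooming = unname(tb$fractions["grooming"]),
          freq_grooming = unname(tb$frequencies["grooming"]))
      },
      distance = c(total_distance_mm = total_distance(t)),
      position = {
        zm <- zone_metrics(e, t, division)
        c(frac_center = unname(zm$fractions["center"]),
          frac_perimeter = unname(zm$fractions["perimeter"]))
      },
      clusters = {
        tb <- time_budget(e, map)
        c(stats::setNames(tb$fractions, paste0("frac_", names(tb$fractions))),
          stats::setNames(tb$frequencies,
                          paste0("freq_", names(tb$frequencies))))
      })
  }
  X <- do.call(rbind, lapply(subs$animal_id, feat_row))
  out <- cbind(subs[, c("animal_id", "genotype", "sex")],
               as.data.frame(X, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  if (anyNA(out)) stop("feature table contains missing values", call. = FALSE)
  structure(out, feature_set = feature_set,
            class = c("feature_table", "data.frame"))
}

#' @keywords internal
feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features),
                               c("animal_id", "genotype", "sex")),
                     drop = FALSE])
}

# z-score columns; constant columns get unit scale (they carry no signal
# but must not produce NaN)
zscore_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}
zscore_apply <- function(X, zs) sweep(sweep(X, 2, zs$mu), 2, zs$sd, "/")

# Fit the Gaussian LDA machinery on a standardized matrix: class means,
# pooled within-class covariance shrunk toward nu*I with the smallest
# shrinkage weight from a fixed ladder that is well conditioned, log class
# priors (class proportions), and up to (k-1) discriminant axes from the
# eigen-decomposition of solve(Sw) %*% Sb.
lda_core <- function(X, y) {
  y <- factor(y)
  k <- nlevels(y); p <- ncol(X); n <- nrow(X)
  if (k < 2L) stop("need at least 2 classes", call. = FALSE)
  means <- do.call(rbind, lapply(levels(y), function(g)
    colMeans(X[y == g, , drop = FALSE])))
  rownames(means) <- levels(y)
  Sw <- matrix(0, p, p)
  for (g in levels(y)) {
    Xg <- X[y == g, , drop = FALSE]
    if (nrow(Xg) > 1L)
      Sw <- Sw + crossprod(sweep(Xg, 2, colMeans(Xg)))
  }
  Sw <- Sw / max(1L, n - k)
  nu <- mean(diag(Sw)); if (!is.finite(nu) || nu <= 0) nu <- 1
  lambda_used <- NA_real_
  for (lambda in c(0, 1e-4, 1e-3, 1e-2, 0.1, 0.25, 0.5, 1)) {
    S <- (1 - lambda) * Sw + lambda * nu * diag(p)
    ok <- tryCatch({
      R <- chol(S)
      rcond(R) > 1e-8
    }, error = function(e) FALSE)
    if (ok) { lambda_used <- lambda; Sw_reg <- S; break }
  }
  if (is.na(lambda_used)) { lambda_used <- 1; Sw_reg <- nu * diag(p) }
  if (lambda_used > 0)
    message(sprintf("lda: within-class covariance shrunk (lambda = %g)",
                    lambda_used))
  Swi <- chol2inv(chol(Sw_reg))
  grand <- colMeans(X)
  Sb <- matrix(0, p, p)
  for (g in levels(y)) {
    d <- means[g, ] - grand
    Sb <- Sb + sum(y == g) * tcrossprod(d)
  }
  Sb <- Sb / n
  e <- eigen(Swi %*% Sb)
  ord <- order(Re(e$values), decreasing = TRUE)
  naxes <- min(k - 1L, p)
  W <- Re(e$vectors[, ord[seq_len(naxes)], drop = FALSE])
  # deterministic axis sign: first nonzero loading positive
  for (j in seq_len(ncol(W))) {
    nz <- which(abs(W[, j]) > 1e-12)[1]
    if (!is.na(nz) && W[nz, j] < 0) W[, j] <- -W[, j]
  }
  colnames(W) <- paste0("LD", seq_len(ncol(W)))
  list(levels = levels(y), means = means, Swi = Swi, W = W,
       log_prior = log(as.numeric(table(y)) / n), lambda = lambda_used)
}

lda_predict <- function(fit, X) {
  scores <- vapply(seq_along(fit$levels), function(gi) {
    m <- fit$means[gi, ]
    drop(X %*% (fit$Swi %*% m)) - 0.5 * drop(m %*% fit$Swi %*% m) +
      fit$log_prior[gi]
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))
  fit$levels[max.col(scores, ties.method = "first")]
}

#' Fit an LDA projection on a feature table
#'
#' Standardizes features (per-column z-score), fits a shrinkage-regularized
#' linear discriminant model on genotype labels, and returns the per-animal
#' coordinates on the (at most 2, for 3 classes) discriminant axes. Axis
#' signs are fixed deterministically.
#'
#' @param features A [build_features()] table (one sex).
#' @return Object of class `lda_fit` with `projection` (data.frame:
#'   `animal_id`, `genotype`, `LD1`, `LD2`...), `fit` internals and
#'   `shrinkage` (lambda used).
#' @export
fit_lda <- function(features) {
  stopifnot(inherits(features, "feature_table") || is.data.frame(features))
  y <- features$genotype
  if (min(table(y)) < 3L)
    stop("need at least 3 animals per class", call. = FALSE)
  X <- feature_matrix(features)
  zs <- zscore_fit(X)
  Z <- zscore_apply(X, zs)
  fit <- lda_core(Z, y)
  proj <- Z %*% fit$W
  structure(list(projection = cbind(
                   features[, c("animal_id", "genotype")],
                   as.data.frame(proj)),
                 fit = fit, zscore = zs, shrinkage = fit$lambda),
            class = "lda_fit")
}

#' Leave-one-out genotype discrimination
#'
#' Each animal is predicted by an LDA fit on all others (standardization and
#' shrinkage re-estimated inside every fold). The confusion matrix is
#' row-normalized by true-class counts and the discrimination score is the
#' mean of its diagonal (mean per-class recall); overall accuracy is also
#' reported. Stratified k-fold CV is available for larger cohorts.
#'
#' @param features A [build_features()] table (one sex).
#' @param cv `"loo"` (default) or `"kfold"`.
#' @param k Folds for `"kfold"`.
#' @param seed Seed for the k-fold shuffle (unused by LOO).
#' @return Object of class `discrimination_result`: `confusion` (3x3
#'   row-normalized), `discrimination`, `accuracy`, `predicted`,
#'   `projection` (from the full-data fit).
#' @export
evaluate_discrimination <- function(features, cv = c("loo", "kfold"), k = 5,
                                    seed = 1) {
  cv <- match.arg(cv)
  y <- factor(features$genotype)
  X <- feature_matrix(features)
  n <- nrow(X)
  folds <- if (cv == "loo") as.list(seq_len(n)) else
    with_seed(seed, split(sample(seq_len(n)),
                          rep(seq_len(k), length.out = n)))
  pred <- character(n)
  for (f in folds) {
    train <- setdiff(seq_len(n), f)
    ytr <- droplevels(y[train])
    if (nlevels(ytr) < nlevels(y))
      stop("a class is absent from training in the fold holding out: ",
           paste(features$animal_id[f], collapse = ", "), call. = FALSE)
    if (min(table(ytr)) < 2L)
      stop("fewer than 2 training animals in a class for the fold holding out: ",
           paste(features$animal_id[f], collapse = ", "), call. = FALSE)
    zs <- zscore_fit(X[train, , drop = FALSE])
    fit <- suppressMessages(lda_core(zscore_apply(X[train, , drop = FALSE], zs),
                                     ytr))
    pred[f] <- lda_predict(fit, zscore_apply(X[f, , drop = FALSE], zs))
  }
  lev <- levels(y)
  conf <- table(factor(y, levels = lev), factor(pred, levels = lev))
  conf_norm <- unclass(conf) / rowSums(conf)
  structure(list(confusion = conf_norm,
                 discrimination = mean(diag(conf_norm)),
                 accuracy = mean(pred == as.character(y)),
                 predicted = data.frame(animal_id = features$animal_id,
                                        genotype = as.character(y),
                                        predicted = pred,
                                        stringsAsFactors = FALSE),
                 projection = suppressMessages(fit_lda(features))$projection,
                 cv = cv),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result> %s CV: discrimination %.3f (accuracy %.3f)\n",
              x$cv, x$discrimination, x$accuracy))
  print(round(x$confusion, 2))
  invisible(x)
}
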