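#' Canonical feature-table columns
#'
#' The 16 per-animal profile variables used for the all-animal unsupervised
#' discrimination stage: total occurrences of sexual behaviors, percent
#' weight variation, percent corticosterone metabolite variation, total
#' distance traveled, total roaming entropy, total occurrences of
#' defensive / maintenance / aggressive behaviors, total preference for the
#' open area, total occurrences of affiliative behaviors, delay-discounting
#' AUC, hub centrality in the aggression network, reversed-task flexibility
#' score, last-20-min gambling preference, mean reward latency in the
#' gambling task, and Blanchard dominance score.
#'
#' @return character vector of column names in canonical order.
#' @export
feature_columns <- function() {
  c("Sexual", "Weight", "Corticosterone", "Distance", "Entropy",
    "Defensive", "Maintenance", "Aggressive", "Pref.open.area",
    "Affiliative", "AUC.DDT", "HUB.agg", "Flexibility", "RGT",
    "Latency.RGT", "Blanchard")
}

#' Assemble and validate the per-animal feature table
#'
#' @param scores data.frame with one row per animal containing all columns
#'   of [feature_columns()], a `genotype` column, and animal ids as row
#'   names (or an `animal` column).
#' @return data.frame of class `feature_table` with the canonical column
#'   order (genotype last). Any missing cell is an error naming the animal
#'   and column: the discrimination stage cannot handle missing data.
#' @export
build_feature_table <- function(scores) {
  if ("animal" %in% names(scores)) {
    rownames(scores) <- scores$animal
    scores$animal <- NULL
  }
  cols <- feature_columns()
  missing_cols <- setdiff(c(cols, "genotype"), names(scores))
  if (length(missing_cols))
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  out <- scores[, c(cols, "genotype")]
  for (cl in cols) {
    bad <- which(!is.finite(out[[cl]]))
    if (length(bad))
      stop("missing value for animal ", rownames(out)[bad[1]],
           ", column ", cl)
  }
  out$genotype <- factor(out$genotype)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Wilcoxon rank-sum W statistic (R convention)
#'
#' W is the sum of the mid-ranks of `x` in the pooled ranking minus
#' n_x (n_x + 1) / 2, as reported by R. The two-sided p-value uses the
#' exact distribution for small tie-free samples and the normal
#' approximation with tie correction otherwise (delegated to
#' [stats::wilcox.test()]).
#'
#' @param x,y two samples.
#' @return list with `W` and `p`.
#' @export
#' @examples
#' rank_sum_W(1:3, 4:6)$W  # 0: complete separation, x low
rank_sum_W <- function(x, y) {
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  list(W = W, p = p)
}

#' One-sample t-test against a theoretical value
#'
#' @param x sample; @param mu theoretical value (e.g. 50 for chance-level
#'   percent preference).
#' @return list with `t`, `p`, `conf.int`.
#' @export
t_vs_theoretical <- function(x, mu) {
  ht <- stats::t.test(x, mu = mu)
  list(t = unname(ht$statistic), p = ht$p.value, conf.int = ht$conf.int)
}

#' Sign test against a theoretical value
#'
#' Exact binomial sign test on the signs of `x - mu` (zeros dropped).
#'
#' @param x sample; @param mu theoretical value.
#' @return list with `S` (positive signs), `n`, `p`.
#' @export
sign_test <- function(x, mu) {
  s <- sign(x - mu)
  s <- s[s != 0]
  ht <- stats::binom.test(sum(s > 0), length(s))
  list(S = sum(s > 0), n = length(s), p = ht$p.value)
}

#' Spearman rank correlation
#'
#' Mid-ranks then Pearson correlation on the ranks.
#'
#' @param x,y paired samples.
#' @return list with `rho` and `p` (from [stats::cor.test()]).
#' @export
spearman_rho <- function(x, y) {
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Random-forest genotype discrimination with leave-one-out validation
#'
#' For each of `n_runs` seeded runs, a leave-one-out cross-validation of a
#' random forest predicting the genotype from the feature table (accuracy =
#' fraction of held-out animals predicted correctly), plus the Gini (mean
#' decrease in impurity) importance of each variable from a forest fit on
#' the full table. A k-means clustering (k = 4 by default) of the
#' per-variable importance profiles across runs groups the variables by
#' importance; clusters are relabeled in decreasing order of mean
#' importance so cluster 1 is always the top-importance group.
#'
#' @param features a [build_feature_table()] table.
#' @param n_runs number of runs (default 100).
#' @param ntree trees per forest (default 500).
#' @param k number of importance clusters (default 4).
#' @param seed master seed; run `i` uses `seed + i`.
#' @return object of class `rf_discrimination`: `accuracy` (per run),
#'   `mean_accuracy`, `sd_accuracy`, `importance` (variables x runs Gini
#'   matrix), `clusters` (named integer, 1 = most important),
#'   `cluster_means`.
#' @export
rf_discriminate <- function(features, n_runs = 100, ntree = 500, k = 4,
                            seed = 1) {
  stopifnot(inherits(features, "feature_table"))
  y <- features$genotype
  if (nlevels(droplevels(y)) < 2)
    stop("discrimination requires at least two genotype labels")
  if (min(table(y)) < 2)
    stop("discrimination requires >= 2 animals per label")
  x <- as.data.frame(features[, feature_columns()])
  n <- nrow(x)
  acc <- numeric(n_runs)
  imp <- matrix(NA_real_, length(feature_columns()), n_runs,
                dimnames = list(feature_columns(), NULL))
  for (run in seq_len(n_runs)) {
    set.seed(seed + run)
    pred <- factor(rep(NA_character_, n), levels = levels(y))
    for (i in seq_len(n)) {
      fit <- randomForest::randomForest(x[-i, , drop = FALSE], y[-i],
                                        ntree = ntree)
      pred[i] <- stats::predict(fit, x[i, , drop = FALSE])
    }
    acc[run] <- mean(pred == y)
    full <- randomForest::randomForest(x, y, ntree = ntree,
                                       importance = FALSE)
    imp[, run] <- full$importance[, "MeanDecreaseGini"]
  }
  set.seed(seed)
  km <- stats::kmeans(imp, centers = min(k, nrow(imp)), nstart = 25)
  ord <- order(tapply(rowMeans(imp), km$cluster, mean), decreasing = TRUE)
  relabel <- match(km$cluster, ord)
  names(relabel) <- rownames(imp)
  structure(list(accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc), importance = imp,
                 clusters = relabel,
                 cluster_means = sort(tapply(rowMeans(imp), relabel, mean),
                                      decreasing = TRUE),
                 n = n, n_runs = n_runs, ntree = ntree, seed = seed),
            class = "rf_discrimination")
}

#' @export
print.rf_discrimination <- function(x, ...) {
  cat(sprintf("Random-forest genotype discrimination: %d animals, %d runs\n",
              x$n, x$n_runs))
  cat(sprintf("mean LOO accuracy %.1f%% (SD %.2f)\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy))
  cat("top importance cluster:",
      paste(names(x$clusters)[x$clusters == 1], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rf_discrimination <- function(object, ...) {
  imp <- rowMeans(object$importance)
  data.frame(variable = names(imp), mean_gini = unname(imp),
             cluster = unname(object$clusters[names(imp)]),
             row.names = NULL)[order(-imp), ]
}

#' @export
plot.rf_discrimination <- function(x, ...) {
  ord <- order(rowMeans(x$importance), decreasing = TRUE)
  graphics::boxplot(t(x$importance[ord, , drop = FALSE]), las = 2,
                    ylab = "Gini importance",
                    main = "Variable importance over runs", ...)
  invisible(x)
}

#' Principal component analysis of the feature table
#'
#' Centered, unit-variance PCA of the numeric profile variables, with
#' per-variable contributions to each dimension (squared loading share, in
#' percent; columns sum to 100), per-dimension variance explained, group
#' centroids and 0.95 normal confidence ellipses for plotting.
#'
#' @param features a [build_feature_table()] table.
#' @return object of class `pca_profile`: `prcomp`, `scores`,
#'   `var_explained` (%), `contributions` (variables x dims, %),
#'   `centroids`, `ellipses` (list of coordinate matrices per genotype).
#' @export
pca_profile <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  x <- as.matrix(as.data.frame(features[, feature_columns()]))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  contrib <- sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/") * 100
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  g <- features$genotype
  centroids <- apply(pc$x[, 1:2, drop = FALSE], 2,
                     function(cc) tapply(cc, g, mean))
  ellipses <- lapply(levels(g), function(lv) {
    pts <- pc$x[g == lv, 1:2, drop = FALSE]
    if (nrow(pts) < 3) return(NULL)
    ctr <- colMeans(pts)
    cv <- stats::cov(pts)
    r <- sqrt(stats::qchisq(0.95, df = 2))
    theta <- seq(0, 2 * pi, length.out = 100)
    circ <- cbind(cos(theta), sin(theta)) * r
    ei <- eigen(cv)
    t(ctr + t(circ %*% diag(sqrt(pmax(ei$values, 0))) %*% t(ei$vectors)))
  })
  names(ellipses) <- levels(g)
  structure(list(prcomp = pc, scores = pc$x, var_explained = ve,
                 contributions = contrib, centroids = centroids,
                 ellipses = ellipses, genotype = g),
            class = "pca_profile")
}

#' @export
print.pca_profile <- function(x, ...) {
  cat("PCA of the feature table\n")
  cat(sprintf("dimension 1: %.1f%% of variance; dimension 2: %.1f%%\n",
              x$var_explained[1], x$var_explained[2]))
  top <- sort(x$contributions[, 1], decreasing = TRUE)[1:5]
  cat("top dimension-1 contributors:",
      paste(sprintf("%s (%.1f%%)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pca_profile <- function(x, ...) {
  g <- x$genotype
  cols <- c("purple", "goldenrod")[as.integer(g)]
  plot(x$scores[, 1], x$scores[, 2], col = cols, pch = 19,
       xlab = sprintf("Dim 1 (%.1f%%)", x$var_explained[1]),
       ylab = sprintf("Dim 2 (%.1f%%)", x$var_explained[2]), ...)
  for (i in seq_along(x$ellipses))
    if (!is.null(x$ellipses[[i]]))
      graphics::lines(x$ellipses[[i]], col = c("purple", "goldenrod")[i])
  graphics::points(x$centroids, pch = 17, cex = 2,
                   col = c("purple", "goldenrod"))
  invisible(x)
}
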