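# Minimal multinomial gradient-boosted trees.  No boosted-tree package is
# available offline, so the stand-in classifier (the published one cannot be
# re-derived from the paper) is implemented here: softmax boosting with small
# exact-greedy regression trees, one per class per round.

# fit one SSE regression tree on residuals; nodes stored in a data.frame
.fit_tree <- function(X, r, depth, min_obs = 10, n_cuts = 16) {
  nodes <- data.frame(feature = NA_integer_, threshold = NA_real_,
                      left = NA_integer_, right = NA_integer_,
                      value = mean(r))
  grow <- function(rows, d, node_id) {
    if (d >= depth || length(rows) < 2 * min_obs) return(invisible())
    best <- list(gain = 1e-9)
    for (j in seq_len(ncol(X))) {
      xj <- X[rows, j]
      cand <- unique(stats::quantile(xj, probs = seq_len(n_cuts) /
                                       (n_cuts + 1), names = FALSE,
                                     type = 1))
      cand <- cand[is.finite(cand)]
      for (cut in cand) {
        lf <- xj <= cut
        nl <- sum(lf)
        if (nl < min_obs || length(rows) - nl < min_obs) next
        rl <- r[rows[lf]]; rr <- r[rows[!lf]]
        gain <- sum(rl)^2 / nl + sum(rr)^2 / (length(rows) - nl) -
          sum(r[rows])^2 / length(rows)
        if (gain > best$gain) best <- list(gain = gain, j = j, cut = cut)
      }
    }
    if (is.null(best$j)) return(invisible())
    lf <- X[rows, best$j] <= best$cut
    nodes[c(node_id), c("feature", "threshold")] <<-
      list(best$j, best$cut)
    lid <- nrow(nodes) + 1L; rid <- nrow(nodes) + 2L
    nodes[lid, ] <<- list(NA_integer_, NA_real_, NA_integer_, NA_integer_,
                          mean(r[rows[lf]]))
    nodes[rid, ] <<- list(NA_integer_, NA_real_, NA_integer_, NA_integer_,
                          mean(r[rows[!lf]]))
    nodes$left[node_id] <<- lid
    nodes$right[node_id] <<- rid
    grow(rows[lf], d + 1L, lid)
    grow(rows[!lf], d + 1L, rid)
    invisible()
  }
  grow(seq_len(nrow(X)), 0L, 1L)
  nodes
}

.tree_leaf_of <- function(nodes, X) {
  cur <- rep(1L, nrow(X))
  repeat {
    split <- !is.na(nodes$feature[cur])
    if (!any(split)) break
    j <- nodes$feature[cur]
    go_left <- split & X[cbind(seq_len(nrow(X)), j)] <= nodes$threshold[cur]
    nxt <- cur
    nxt[go_left] <- nodes$left[cur[go_left]]
    nxt[split & !go_left] <- nodes$right[cur[split & !go_left]]
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

#' Train the gradient-boosted mode classifier
#'
#' Multinomial (softmax) gradient boosting with exact-greedy regression
#' trees, fit on labelled epoch features with a fixed seed.  Defaults follow
#' common boosted-tree practice (500 rounds, depth 3, learning rate 0.05).
#' Returns a serialisable model with a held-out training report
#' (per-class precision/recall).
#'
#' @param features Labelled feature table containing [MS_FEATURES] columns
#'   and a `mode` column (>= 2 classes).
#' @param seed Integer seed (subsampling of the held-out split).
#' @param n_trees,depth,learning_rate Boosting hyper-parameters.
#' @param holdout Fraction held out for the training report.
#' @return Object of class `ms_gbt` with elements `trees`, `classes`,
#'   `features`, `report`.
#' @export
train_model <- function(features, seed = 1L, n_trees = 500, depth = 3,
                        learning_rate = 0.05, holdout = 0.25) {
  y <- droplevels(factor(features$mode))
  if (nlevels(y) < 2) stop("need >= 2 classes to train", call. = FALSE)
  X <- as.matrix(features[MS_FEATURES])
  X[!is.finite(X)] <- 1e6  # rail_dist Inf -> large finite
  withr::with_seed(as.integer(seed), {
    n <- nrow(X)
    te <- sample(n, max(1, round(holdout * n)))
    tr <- setdiff(seq_len(n), te)
    K <- nlevels(y)
    Y <- outer(as.integer(y[tr]), seq_len(K), "==") * 1
    F <- matrix(0, length(tr), K)
    trees <- vector("list", n_trees)
    for (b in seq_len(n_trees)) {
      P <- exp(F - apply(F, 1, max))
      P <- P / rowSums(P)
      round_trees <- vector("list", K)
      for (k in seq_len(K)) {
        r <- Y[, k] - P[, k]
        tree <- .fit_tree(X[tr, , drop = FALSE], r, depth)
        leaf <- .tree_leaf_of(tree, X[tr, , drop = FALSE])
        # multinomial leaf update (Friedman et al.)
        num <- tapply(r, leaf, sum)
        den <- tapply(abs(r) * (1 - abs(r)), leaf, sum)
        val <- (K - 1) / K * num / pmax(den, 1e-8)
        tree$value <- 0
        tree$value[as.integer(names(val))] <- val
        tree$value[!is.na(tree$feature)] <- 0
        F[, k] <- F[, k] + learning_rate * tree$value[leaf]
        round_trees[[k]] <- tree
      }
      trees[[b]] <- round_trees
    }
    model <- structure(list(trees = trees, classes = levels(y),
                            features = MS_FEATURES, lr = learning_rate),
                       class = "ms_gbt")
    pred <- predict(model, features[te, , drop = FALSE])
    tab <- table(truth = y[te], pred = factor(pred, levels(y)))
    prec <- diag(tab) / pmax(colSums(tab), 1)
    rec <- diag(tab) / pmax(rowSums(tab), 1)
    model$report <- list(confusion = tab, precision = prec, recall = rec,
                         accuracy = sum(diag(tab)) / sum(tab),
                         n_train = length(tr), n_test = length(te))
    model
  })
}

#' @export
predict.ms_gbt <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[object$features])
  X[!is.finite(X)] <- 1e6
  K <- length(object$classes)
  F <- matrix(0, nrow(X), K)
  for (rt in object$trees)
    for (k in seq_len(K)) {
      tree <- rt[[k]]
      F[, k] <- F[, k] + object$lr * tree$value[.tree_leaf_of(tree, X)]
    }
  if (type == "prob") {
    P <- exp(F - apply(F, 1, max))
    return(P / rowSums(P))
  }
  factor(object$classes[max.col(F, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.ms_gbt <- function(x, ...) {
  cat("<ms_gbt>", length(x$trees), "rounds x", length(x$classes),
      "classes; held-out accuracy",
      round(x$report$accuracy, 3), "\n")
  invisible(x)
}
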