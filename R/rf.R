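# A compact random forest for two-class problems (no suitable forest
# implementation is available in the target environment). CART trees with
# Gini impurity, bootstrap resampling per tree, mtry random candidate
# features per node, grown to purity (nodesize 1) as is standard for
# classification forests. Probabilities are tree-vote fractions.

# Grow one tree on (X, y01); returns parallel node vectors. Splits are at
# midpoints between distinct sorted values; ties in impurity go to the first
# (lowest-index) candidate encountered.
grow_tree <- function(X, y01, mtry, nodesize = 1L) {
  p <- ncol(X)
  var <- integer(0); split <- numeric(0)
  left <- integer(0); right <- integer(0); pred <- numeric(0)
  new_node <- function() {
    var[length(var) + 1L] <<- NA_integer_
    split[length(split) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_
    right[length(right) + 1L] <<- NA_integer_
    pred[length(pred) + 1L] <<- NA_real_
    length(var)
  }
  root <- new_node()
  stack <- list(list(id = root, rows = seq_len(nrow(X))))
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    rows <- nd$rows
    yb <- y01[rows]
    m <- mean(yb)
    if (length(rows) <= nodesize || m == 0 || m == 1) {
      pred[nd$id] <- m
      next
    }
    vars <- sample.int(p, mtry)
    best <- NULL; best_imp <- Inf
    n <- length(rows)
    for (v in vars) {
      xv <- X[rows, v]
      o <- order(xv)
      xs <- xv[o]; ys <- yb[o]
      distinct <- which(xs[-n] < xs[-1])
      if (length(distinct) == 0L) next
      c1 <- cumsum(ys)[distinct]
      nl <- distinct; nr <- n - nl
      c1r <- sum(ys) - c1
      gl <- 2 * (c1 / nl) * (1 - c1 / nl)
      gr <- 2 * (c1r / nr) * (1 - c1r / nr)
      imp <- (nl * gl + nr * gr) / n
      k <- which.min(imp)
      if (imp[k] < best_imp - 1e-12) {
        best_imp <- imp[k]
        cut <- (xs[distinct[k]] + xs[distinct[k] + 1L]) / 2
        best <- list(v = v, cut = cut, lrows = rows[o[seq_len(distinct[k])]],
                     rrows = rows[o[(distinct[k] + 1L):n]])
      }
    }
    if (is.null(best)) {           # all candidate features constant here
      pred[nd$id] <- m
      next
    }
    var[nd$id] <- best$v; split[nd$id] <- best$cut
    l <- new_node(); r <- new_node()
    left[nd$id] <- l; right[nd$id] <- r
    stack[[length(stack) + 1L]] <- list(id = l, rows = best$lrows)
    stack[[length(stack) + 1L]] <- list(id = r, rows = best$rrows)
  }
  list(var = var, split = split, left = left, right = right, pred = pred)
}

predict_tree <- function(tree, X) {
  apply(X, 1, function(x) {
    i <- 1L
    while (is.na(tree$pred[i]))
      i <- if (x[tree$var[i]] <= tree$split[i]) tree$left[i] else tree$right[i]
    tree$pred[i]
  })
}

#' Fit a random forest classifier (two classes)
#'
#' @param X Numeric feature matrix.
#' @param y Factor with two levels; the second level is the positive class.
#' @param ntree Number of trees (default 500).
#' @param mtry Candidate features per split (default `floor(sqrt(p))`).
#' @param nodesize Minimum node size to attempt a split (default 1).
#' @param seed Integer seed (forest growth is deterministic given it).
#' @return An object of class `bv_rf`.
#' @export
fit_random_forest <- function(X, y, ntree = 500L, mtry = NULL,
                              nodesize = 1L, seed = 1L) {
  stopifnot(is.matrix(X), nlevels(y) == 2L, nrow(X) == length(y))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  y01 <- as.integer(y) - 1L
  n <- nrow(X)
  trees <- with_local_seed(seed, lapply(seq_len(ntree), function(b) {
    rows <- sample.int(n, n, replace = TRUE)
    grow_tree(X[rows, , drop = FALSE], y01[rows], mtry, nodesize)
  }))
  structure(list(trees = trees, levels = levels(y), mtry = mtry),
            class = "bv_rf")
}

#' Predict class probabilities from a [fit_random_forest()] model
#' @param object A `bv_rf`.
#' @param newdata Numeric matrix with the training columns.
#' @param ... Unused.
#' @return Vector of probabilities of the positive (second) level:
#'   the fraction of tree votes.
#' @export
predict.bv_rf <- function(object, newdata, ...) {
  votes <- vapply(object$trees,
                  function(tr) as.numeric(predict_tree(tr, newdata) >= 0.5),
                  numeric(nrow(newdata)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  rowMeans(votes)
}
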