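#' Hyperparameters for the boosted-tree classifier
#'
#' @param eta Learning rate (shrinkage) in (0, 1].
#' @param max_depth Maximum tree depth (>= 1; depth 1 is a stump).
#' @param gamma Per-leaf complexity penalty `gamma` (>= 0): a split is kept
#'   only if its objective gain exceeds `gamma`.
#' @param lambda_reg L2 penalty `lambda` on leaf weights (>= 0).
#' @param n_rounds Number of boosting rounds (>= 1).
#' @param min_child_hessian Minimum summed Hessian per child leaf; guards
#'   against near-singular `H + lambda` leaves.
#' @return Object of class `"gbt_params"`.
#' @export
gbt_params <- function(eta = 0.1, max_depth = 4, gamma = 0, lambda_reg = 1,
                       n_rounds = 100, min_child_hessian = 1e-3) {
  if (!(eta > 0 && eta <= 1)) stop("eta must be in (0, 1]", call. = FALSE)
  if (gamma < 0 || lambda_reg < 0) {
    stop("gamma and lambda_reg must be >= 0", call. = FALSE)
  }
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (n_rounds < 1) stop("n_rounds must be >= 1", call. = FALSE)
  structure(list(eta = eta, max_depth = as.integer(max_depth),
                 gamma = gamma, lambda_reg = lambda_reg,
                 n_rounds = as.integer(n_rounds),
                 min_child_hessian = min_child_hessian),
            class = "gbt_params")
}

#' Softmax gradients and Hessians
#'
#' First- and second-order derivatives of the multi-class log loss with
#' respect to the raw (pre-softmax) scores: for class c,
#' `g = p_c - 1[y = c]` and `h = p_c (1 - p_c)` with
#' `p = softmax(raw_scores)`. Softmax is computed with row-max
#' stabilization.
#'
#' @param labels Integer class indices in `1..C` (or a factor).
#' @param raw_scores Numeric n x C matrix of raw scores.
#' @return List with `g` and `h`, both n x C matrices; `h >= 0`.
#' @export
softmax_grad_hess <- function(labels, raw_scores) {
  if (any(!is.finite(raw_scores))) {
    stop("non-finite raw scores", call. = FALSE)
  }
  if (is.factor(labels)) labels <- as.integer(labels)
  p <- .softmax(raw_scores)
  n <- nrow(p); C <- ncol(p)
  if (any(labels < 1 | labels > C)) stop("label out of range", call. = FALSE)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), labels)] <- 1
  list(g = p - Y, h = p * (1 - p))
}

.softmax <- function(raw) {
  z <- exp(raw - apply(raw, 1, max))
  z / rowSums(z)
}

#' Optimal leaf weight
#'
#' The weight minimizing the second-order objective for a leaf with summed
#' gradient `G` and summed Hessian `H`: `w* = -G / (H + lambda)`.
#'
#' @param G,H Summed gradient and Hessian of the leaf's instances.
#' @param lambda_reg L2 penalty.
#' @return The optimal weight.
#' @examples
#' leaf_weight(2, 3, 1)  # -0.5
#' @export
leaf_weight <- function(G, H, lambda_reg) {
  if (H + lambda_reg <= 0) {
    stop("degenerate leaf: H + lambda must be positive", call. = FALSE)
  }
  -G / (H + lambda_reg)
}

#' Structure score of a tree partition
#'
#' The optimized regularized objective of a partition of the instances
#' into `T` leaves: `-1/2 * sum_j G_j^2 / (H_j + lambda) + gamma * T`.
#' Lower is better; the gain of a split is the parent score minus the sum
#' of the children's scores.
#'
#' @param leaf_assign Integer leaf index per instance (1..T, every leaf
#'   non-empty).
#' @param g,h Per-instance gradients and Hessians.
#' @param lambda_reg,gamma Regularization parameters.
#' @return The structure score (scalar).
#' @export
structure_score <- function(leaf_assign, g, h, lambda_reg = 0, gamma = 0) {
  Tn <- max(leaf_assign)
  if (!setequal(unique(leaf_assign), seq_len(Tn))) {
    stop("degenerate partition: empty leaf", call. = FALSE)
  }
  Gj <- tapply(g, leaf_assign, sum)
  Hj <- tapply(h, leaf_assign, sum)
  if (any(Hj + lambda_reg <= 0)) {
    stop("degenerate leaf: H + lambda must be positive", call. = FALSE)
  }
  -0.5 * sum(Gj^2 / (Hj + lambda_reg)) + gamma * Tn
}

# Best split of the instance set `idx` over all (feature, threshold) pairs.
# Gain = 1/2 [G_L^2/(H_L+l) + G_R^2/(H_R+l) - G^2/(H+l)] - gamma.
# Ties: which.max keeps the lowest threshold within a feature (sorted
# scan); strict > keeps the lowest feature index across features.
.best_split <- function(X, g, h, idx, params) {
  G <- sum(g[idx]); H <- sum(h[idx])
  lam <- params$lambda_reg
  parent <- G^2 / (H + lam)
  best <- list(gain = 0)
  for (f in seq_len(ncol(X))) {
    xf <- X[idx, f]
    o <- order(xf, method = "radix")
    xs <- xf[o]
    cand <- which(diff(xs) > 0)
    if (!length(cand)) next
    gs <- cumsum(g[idx][o]); hs <- cumsum(h[idx][o])
    GL <- gs[cand]; HL <- hs[cand]
    GR <- G - GL; HR <- H - HL
    ok <- HL >= params$min_child_hessian & HR >= params$min_child_hessian
    if (!any(ok)) next
    gain <- 0.5 * (GL^2 / (HL + lam) + GR^2 / (HR + lam) - parent) -
      params$gamma
    gain[!ok] <- -Inf
    j <- which.max(gain)
    # tie tolerance: mathematically equal gains (e.g. two features that
    # induce the same partition) must break to the lowest feature index
    # regardless of summation rounding
    tol <- 1e-10 * max(1, abs(gain[j]))
    if (gain[j] > best$gain + tol) {
      thr <- (xs[cand[j]] + xs[cand[j] + 1]) / 2
      best <- list(gain = gain[j], feature = f, threshold = thr)
    }
  }
  best
}

#' Grow a single regression tree on gradient statistics
#'
#' Greedy depth-first CART growth: at each node the (feature, threshold)
#' pair maximizing the structure-score gain is chosen by exact enumeration
#' over midpoints of adjacent sorted feature values; growth stops at
#' `max_depth`, non-positive gain, or when a child would fall below
#' `min_child_hessian`. Leaf weights are the optimal `-G/(H + lambda)`.
#' All-constant features yield a single-leaf tree.
#'
#' @param X Numeric feature matrix (n x d).
#' @param g,h Per-instance gradient and Hessian vectors.
#' @param params A [gbt_params()] object.
#' @return A tree: list of node records (fields `is_leaf`, `feature`,
#'   `threshold`, `left`, `right`, `weight`, `G`, `H`, `n`), node 1 the
#'   root, with attribute `n_leaves`.
#' @export
grow_tree <- function(X, g, h, params = gbt_params()) {
  stopifnot(nrow(X) >= 1, length(g) == nrow(X), length(h) == nrow(X))
  nodes <- list()
  new_node <- function(rec) {
    nodes[[length(nodes) + 1]] <<- rec
    length(nodes)
  }
  build <- function(idx, depth) {
    G <- sum(g[idx]); H <- sum(h[idx])
    make_leaf <- function() {
      new_node(list(is_leaf = TRUE, feature = NA_integer_,
                    threshold = NA_real_, left = NA_integer_,
                    right = NA_integer_,
                    weight = leaf_weight(G, H, params$lambda_reg),
                    G = G, H = H, n = length(idx)))
    }
    if (depth >= params$max_depth) return(make_leaf())
    sp <- .best_split(X, g, h, idx, params)
    if (sp$gain <= 0) return(make_leaf())
    id <- new_node(list(is_leaf = FALSE, feature = sp$feature,
                        threshold = sp$threshold, left = NA_integer_,
                        right = NA_integer_, weight = NA_real_,
                        G = G, H = H, n = length(idx)))
    goes_left <- X[idx, sp$feature] < sp$threshold
    nodes[[id]]$left <<- build(idx[goes_left], depth + 1)
    nodes[[id]]$right <<- build(idx[!goes_left], depth + 1)
    id
  }
  build(seq_len(nrow(X)), 0)
  attr(nodes, "n_leaves") <- sum(vapply(nodes, `[[`, TRUE, "is_leaf"))
  class(nodes) <- "gbt_tree"
  nodes
}

# Vectorized routing: returns the leaf weight for every row of X.
.predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  recurse <- function(node_id, idx) {
    if (!length(idx)) return(invisible())
    nd <- tree[[node_id]]
    if (nd$is_leaf) {
      out[idx] <<- nd$weight
    } else {
      left <- X[idx, nd$feature] < nd$threshold
      recurse(nd$left, idx[left])
      recurse(nd$right, idx[!left])
    }
  }
  recurse(1, seq_len(nrow(X)))
  out
}

#' Fit a second-order gradient-boosted tree classifier
#'
#' Multi-class gradient boosting built from scratch: each round fits one
#' regression tree per class to the softmax gradients and Hessians of the
#' current raw scores (one-vs-all trees with softmax coupling), and adds
#' `eta` times the tree output to that class's raw score. Split search is
#' exact greedy (no binning, no subsampling), leaf weights are the
#' second-order optima `-G/(H + lambda)`, and split gains are the
#' structure-score reductions penalized by `gamma` per leaf. The training
#' log records the log loss and the regularized objective (log loss plus
#' `gamma * T + 1/2 * lambda * sum(w^2)` over the applied, shrunken leaf
#' weights) after every round.
#'
#' `gbt()` is the formula interface (`label ~ .` on a data frame with
#' numeric feature columns); `gbt_fit()` takes a feature matrix and a
#' label factor directly.
#'
#' @param formula Model formula; the response is the class label.
#' @param data Data frame with the response and numeric features
#'   (non-numeric feature columns are dropped with a warning).
#' @param x Numeric feature matrix (n x d) with column names.
#' @param y Class labels (factor or character, >= 2 classes present).
#' @param params A [gbt_params()] object.
#' @param ... For `gbt()`: arguments forwarded to [gbt_params()].
#' @return An object of class `"gbt"`: list with `trees` (per round a list
#'   of per-class trees), `classes`, `base_score`, `feature_names`,
#'   `params`, `eval_log` (data frame: round, train_logloss, objective),
#'   and `call`. Methods: [predict.gbt()], `print`, `summary`, `plot`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = c(rnorm(20, -2), rnorm(20, 2)), x2 = rnorm(40),
#'                 y = rep(c("a", "b"), each = 20))
#' m <- gbt(y ~ ., d, n_rounds = 10, max_depth = 2)
#' mean(predict(m, d) == d$y)
#' @export
gbt <- function(formula, data, params = NULL, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  feats <- mf[, -1, drop = FALSE]
  numeric_cols <- vapply(feats, is.numeric, TRUE)
  if (!all(numeric_cols)) {
    warning("dropping non-numeric feature columns: ",
            paste(names(feats)[!numeric_cols], collapse = ", "))
    feats <- feats[, numeric_cols, drop = FALSE]
  }
  if (is.null(params)) params <- gbt_params(...)
  fit <- gbt_fit(as.matrix(feats), y, params)
  fit$call <- match.call()
  fit
}

#' @rdname gbt
#' @export
gbt_fit <- function(x, y, params = gbt_params()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  classes <- levels(droplevels(y))
  C <- length(classes)
  if (C < 2) stop("training requires at least 2 classes", call. = FALSE)
  yi <- as.integer(factor(y, levels = classes))
  n <- nrow(x)
  raw <- matrix(0, n, C)  # base score: 0 raw score per class (uniform prior)
  trees <- list()
  log_rounds <- integer(0); log_ll <- log_obj <- numeric(0)
  penalty <- 0
  n_rounds <- params$n_rounds

  for (r in seq_len(n_rounds)) {
    gh <- softmax_grad_hess(yi, raw)
    round_trees <- vector("list", C)
    for (ci in seq_len(C)) {
      tr <- grow_tree(x, gh$g[, ci], gh$h[, ci], params)
      round_trees[[ci]] <- tr
      raw[, ci] <- raw[, ci] + params$eta * .predict_tree(tr, x)
      leaves <- Filter(function(nd) nd$is_leaf, tr)
      w_applied <- params$eta * vapply(leaves, `[[`, 0, "weight")
      penalty <- penalty + params$gamma * length(leaves) +
        0.5 * params$lambda_reg * sum(w_applied^2)
    }
    trees[[r]] <- round_trees
    p <- .softmax(raw)
    ll <- -sum(log(pmax(p[cbind(seq_len(n), yi)], 1e-15)))
    log_rounds <- c(log_rounds, r)
    log_ll <- c(log_ll, ll / n)
    log_obj <- c(log_obj, ll + penalty)
  }
  structure(list(trees = trees, classes = classes,
                 base_score = rep(0, C),
                 feature_names = colnames(x), params = params,
                 eval_log = data.frame(round = log_rounds,
                                       train_logloss = log_ll,
                                       objective = log_obj),
                 n_train = n, call = sys.call()),
            class = "gbt")
}

.gbt_raw <- function(object, X) {
  n <- nrow(X)
  C <- length(object$classes)
  raw <- matrix(rep(object$base_score, each = n), n, C)
  eta <- object$params$eta
  for (round_trees in object$trees) {
    for (ci in seq_len(C)) {
      raw[, ci] <- raw[, ci] + eta * .predict_tree(round_trees[[ci]], X)
    }
  }
  colnames(raw) <- object$classes
  raw
}

#' Predict from a boosted-tree classifier
#'
#' Class probabilities are the softmax of the per-class summed tree
#' outputs; with no trees (zero rounds) they are uniform.
#'
#' @param object A fitted [gbt()] model.
#' @param newdata Data frame or matrix containing the model's feature
#'   columns (matched by name; schema mismatch is an error).
#' @param type `"class"` (default) for predicted labels, `"prob"` for the
#'   n x C probability matrix, `"raw"` for raw scores.
#' @param ... Unused.
#' @export
predict.gbt <- function(object, newdata,
                        type = c("class", "prob", "raw"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_names, names(newdata))
    if (length(missing_cols)) {
      stop("newdata lacks feature columns: ",
           paste(utils::head(missing_cols, 5), collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    X <- as.matrix(newdata)
    if (!is.null(colnames(X))) {
      if (!all(object$feature_names %in% colnames(X))) {
        stop("newdata lacks required feature columns", call. = FALSE)
      }
      X <- X[, object$feature_names, drop = FALSE]
    } else if (ncol(X) != length(object$feature_names)) {
      stop("newdata has ", ncol(X), " columns; model expects ",
           length(object$feature_names), call. = FALSE)
    }
  }
  if (!is.numeric(X)) stop("features must be numeric", call. = FALSE)
  raw <- .gbt_raw(object, X)
  switch(type,
         raw = raw,
         prob = .softmax(raw),
         class = factor(object$classes[max.col(raw, ties.method = "first")],
                        levels = object$classes))
}

#' @export
print.gbt <- function(x, ...) {
  cat("Second-order gradient-boosted tree classifier\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  rounds: %d | eta %.3g | max_depth %d | lambda %.3g | gamma %.3g\n",
              length(x$trees), x$params$eta, x$params$max_depth,
              x$params$lambda_reg, x$params$gamma))
  cat(sprintf("  features: %d | training rows: %d\n",
              length(x$feature_names), x$n_train))
  if (nrow(x$eval_log)) {
    cat(sprintf("  final train log-loss: %.5f\n",
                x$eval_log$train_logloss[nrow(x$eval_log)]))
  }
  invisible(x)
}

#' @export
summary.gbt <- function(object, ...) {
  n_leaves <- vapply(object$trees, function(rt) {
    sum(vapply(rt, function(tr) attr(tr, "n_leaves"), 0L))
  }, 0L)
  out <- list(model = object,
              leaves_per_round = n_leaves,
              eval_log = object$eval_log)
  class(out) <- "summary.gbt"
  out
}

#' @export
print.summary.gbt <- function(x, ...) {
  print(x$model)
  cat(sprintf("  total leaves: %d (mean %.1f per round over %d classes)\n",
              sum(x$leaves_per_round), mean(x$leaves_per_round),
              length(x$model$classes)))
  cat("  objective by round (first/last 3):\n")
  el <- x$eval_log
  show <- unique(c(utils::head(seq_len(nrow(el)), 3),
                   utils::tail(seq_len(nrow(el)), 3)))
  print(el[show, ], row.names = FALSE)
  invisible(x)
}

#' @export
plot.gbt <- function(x, which = c("objective", "logloss"), ...) {
  which <- match.arg(which)
  el <- x$eval_log
  yv <- if (which == "objective") el$objective else el$train_logloss
  graphics::plot(el$round, yv, type = "l", xlab = "boosting round",
                 ylab = which, main = "Training progress", ...)
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' The full ensemble (parameters, class order, per-tree node records) is
#' written as a JSON document at full numeric precision, so a reloaded
#' model reproduces predictions bit-for-bit.
#'
#' @param object A fitted [gbt()] model.
#' @param path Output / input file path.
#' @export
gbt_save <- function(object, path) {
  ser_tree <- function(tr) {
    lapply(seq_along(tr), function(i) c(list(id = i), tr[[i]]))
  }
  doc <- list(
    format = "specklesense-gbt-1",
    params = unclass(object$params),
    classes = object$classes,
    base_score = object$base_score,
    feature_names = object$feature_names,
    n_train = object$n_train,
    eval_log = object$eval_log,
    trees = lapply(object$trees, function(rt) lapply(rt, ser_tree)))
  # I(17) significant digits: doubles round-trip bit-exactly
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                              na = "null"), path)
  invisible(path)
}

#' @rdname gbt_save
#' @export
gbt_load <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "specklesense-gbt-1")) {
    stop("not a serialized gbt model", call. = FALSE)
  }
  de_tree <- function(nodes) {
    tr <- lapply(nodes, function(nd) {
      list(is_leaf = isTRUE(nd$is_leaf),
           feature = if (is.null(nd$feature)) NA_integer_
                     else as.integer(nd$feature),
           threshold = if (is.null(nd$threshold)) NA_real_
                       else as.numeric(nd$threshold),
           left = if (is.null(nd$left)) NA_integer_ else as.integer(nd$left),
           right = if (is.null(nd$right)) NA_integer_
                   else as.integer(nd$right),
           weight = if (is.null(nd$weight)) NA_real_
                    else as.numeric(nd$weight),
           G = as.numeric(nd$G), H = as.numeric(nd$H),
           n = as.integer(nd$n))
    })
    attr(tr, "n_leaves") <- sum(vapply(tr, `[[`, TRUE, "is_leaf"))
    class(tr) <- "gbt_tree"
    tr
  }
  p <- doc$params
  params <- gbt_params(eta = p$eta, max_depth = p$max_depth,
                       gamma = p$gamma, lambda_reg = p$lambda_reg,
                       n_rounds = p$n_rounds,
                       min_child_hessian = p$min_child_hessian)
  structure(list(
    trees = lapply(doc$trees, function(rt) lapply(rt, de_tree)),
    classes = unlist(doc$classes),
    base_score = unlist(doc$base_score),
    feature_names = unlist(doc$feature_names),
    params = params,
    eval_log = do.call(rbind, lapply(doc$eval_log, as.data.frame)),
    n_train = doc$n_train,
    call = NULL), class = "gbt")
}
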