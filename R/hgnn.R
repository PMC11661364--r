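as_binary01 <- function(labels) {
  if (is.factor(labels)) return(as.integer(labels) - 1L)
  if (is.logical(labels)) return(as.integer(labels))
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1)))
    stop("labels must be binary (0/1, logical, or a two-level factor)",
         call. = FALSE)
  as.integer(labels)
}

#' Threshold-free ROC AUC
#'
#' Rank-based (Mann-Whitney) AUC; ties in the scores are handled by
#' midranks.
#'
#' @param scores numeric classification scores (higher = more positive).
#' @param labels binary labels; positive class = 1 / second factor level.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary01(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classifier metrics: AUC, sensitivity, specificity
#'
#' Sensitivity and specificity are computed at the fixed probability
#' threshold 0.5; the Youden-optimal threshold and its operating point are
#' reported alongside for reference.
#'
#' @param prob predicted probability of the positive class.
#' @param labels binary labels (positive = 1 / second factor level).
#' @param threshold decision threshold for sensitivity/specificity.
#' @return list: `auc`, `sensitivity`, `specificity`, `threshold`,
#'   `youden_threshold`, `youden_sensitivity`, `youden_specificity`,
#'   `prob` (per-subject predicted probability).
#' @export
evaluate <- function(prob, labels, threshold = 0.5) {
  y <- as_binary01(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the evaluation labels",
         call. = FALSE)
  auc <- auc_score(prob, y)
  sens_spec <- function(thr) {
    pred <- as.integer(prob >= thr)
    c(sens = sum(pred == 1L & y == 1L) / sum(y == 1L),
      spec = sum(pred == 0L & y == 0L) / sum(y == 0L))
  }
  at <- sens_spec(threshold)
  cand <- sort(unique(prob))
  youden <- vapply(cand, function(t) sum(sens_spec(t)) - 1, numeric(1))
  thr_y <- cand[which.max(youden)]
  at_y <- sens_spec(thr_y)
  list(auc = auc, sensitivity = unname(at["sens"]),
       specificity = unname(at["spec"]), threshold = threshold,
       youden_threshold = thr_y,
       youden_sensitivity = unname(at_y["sens"]),
       youden_specificity = unname(at_y["spec"]),
       prob = prob)
}

#' Hypergraph neural network configuration
#'
#' Defaults: 2 hyperedge-convolution layers of hidden width 16, dropout
#' 0.3, Adam with learning rate 0.01 and weight decay 5e-4, 400 epochs,
#' k = 12 nodes per continuous-feature hyperedge (the plateau of the
#' k = 5..13 sweep).
#'
#' @param k hyperedge size for continuous features (the sweep range is
#'   5..13).
#' @param layers number of hyperedge-convolution layers (>= 1).
#' @param hidden_width hidden feature width.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param dropout dropout rate on hidden activations during training.
#' @param weight_decay L2 penalty on the layer weights (the customary
#'   default for spectral hypergraph convolution training).
#' @param restarts independent seeded optimization runs whose predicted
#'   probabilities are averaged (init ensembling; 1 = single run).
#' @param seed RNG seed controlling initialization and dropout.
#' @return list of class `hgnn_config`.
#' @export
hgnn_config <- function(k = 12L, layers = 2L, hidden_width = 16L,
                        learning_rate = 0.01, epochs = 400L,
                        dropout = 0.3, weight_decay = 5e-4,
                        restarts = 3L, seed = 1L) {
  stopifnot(layers >= 1L, hidden_width >= 1L, epochs >= 1L,
            dropout >= 0, dropout < 1, learning_rate > 0,
            weight_decay >= 0, restarts >= 1L)
  structure(list(k = as.integer(k), layers = as.integer(layers),
                 hidden_width = as.integer(hidden_width),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs), dropout = dropout,
                 weight_decay = weight_decay, restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "hgnn_config")
}

#' Normalized hypergraph convolution operator
#'
#' The spectral hyperedge-convolution operator
#' `G = Dv^{-1/2} H W De^{-1} H^T Dv^{-1/2}`, where `H` is the incidence
#' matrix, `W = diag(w)` the hyperedge weights, `De` the hyperedge degrees
#' and `Dv` the weighted vertex degrees. One application performs the
#' degree-normalized node -> edge -> node aggregation; `G` is invariant to
#' a global rescaling of the edge weights.
#'
#' @param hg a [hypergraph()].
#' @return dense symmetric n x n matrix.
#' @export
hg_operator <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  H <- hg$incidence
  w <- hg$weights
  de <- Matrix::colSums(H)
  dv <- as.numeric(H %*% w)
  if (any(dv <= 0))
    stop(paste("isolated node(s) with zero hyperedge degree;",
               "include each node in at least one hyperedge",
               "(kNN hyperedges guarantee this since i is in its own edge)"),
         call. = FALSE)
  Hw <- H %*% Matrix::Diagonal(x = w / de)
  G <- Matrix::Diagonal(x = 1 / sqrt(dv)) %*% Hw %*% Matrix::t(H) %*%
    Matrix::Diagonal(x = 1 / sqrt(dv))
  as.matrix(G)
}

hgnn_init <- function(d_in, config) {
  widths <- c(d_in, rep(config$hidden_width, config$layers - 1L), 2L)
  set.seed(config$seed)
  params <- list(W = list(), b = list())
  for (l in seq_len(config$layers)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1L]
    sd <- sqrt(2 / (fan_in + fan_out))  # Glorot
    params$W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, sd = sd),
                            fan_in, fan_out)
    params$b[[l]] <- rep(0, fan_out)
  }
  params
}

#' HGNN forward pass
#'
#' Each layer applies the normalized hypergraph operator (node -> edge ->
#' node aggregation) followed by a learnable linear map; hidden layers use
#' a ReLU nonlinearity and the final layer emits 2-class scores.
#'
#' @param hg a [hypergraph()] or a precomputed operator from
#'   [hg_operator()].
#' @param x n x p node-feature matrix.
#' @param params layer weights as produced by [train_hgnn()] (`$params`).
#' @return n x 2 matrix of class scores (positive class = column 2).
#' @export
hgnn_forward <- function(hg, x, params) {
  G <- if (inherits(hg, "hypergraph")) hg_operator(hg) else as.matrix(hg)
  a <- as.matrix(x)
  L <- length(params$W)
  for (l in seq_len(L)) {
    z <- G %*% a %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(a), length(params$b[[l]]), byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else z
  }
  a
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a spectral HGNN classifier
#'
#' Full-batch training with cross-entropy loss on the training nodes and
#' Adam updates. The validation AUC is monitored every epoch; the kept
#' checkpoint maximizes a 9-epoch moving average of the validation curve
#' past a 25% burn-in (raw per-epoch argmax on a small validation set is
#' badly max-biased), and reported probabilities average the checkpoints
#' within 4 epochs of the selected one. Test metrics are computed once, on
#' the test nodes. All randomness (initialization, dropout) derives from
#' `config$seed`, so a fixed seed and config give identical results.
#'
#' @param hg a [hypergraph()] over all n subjects.
#' @param x n x p node-feature matrix (standardized feature values).
#' @param labels length-n binary labels (positive = 1 / second level).
#' @param splits list of disjoint index vectors `train`, `val`, `test`
#'   (see [split_cohort()]).
#' @param config an [hgnn_config()].
#' @return object of class `hgnn_fit`: `params` (best by validation AUC),
#'   `metrics` (test-set [evaluate()] output), `val_auc`, `best_epoch`,
#'   `history` (per-epoch loss and validation AUC), `config`, `prob`
#'   (probabilities for all nodes under the selected model).
#' @export
train_hgnn <- function(hg, x, labels, splits, config = hgnn_config()) {
  y <- as_binary01(labels)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n)
  tr <- splits$train; va <- splits$val; te <- splits$test
  if (length(intersect(tr, va)) || length(intersect(tr, te)) ||
      length(intersect(va, te)))
    stop("train/val/test index sets must be disjoint", call. = FALSE)
  if (length(unique(y[tr])) < 2L)
    stop("training set contains a single class", call. = FALSE)
  G <- if (inherits(hg, "hypergraph")) hg_operator(hg) else as.matrix(hg)
  runs <- lapply(seq_len(config$restarts), function(r) {
    cfg <- config
    cfg$seed <- config$seed + (r - 1L) * 10007L
    train_hgnn_once(G, x, y, splits, cfg)
  })
  first <- runs[[1]]
  prob <- rowMeans(vapply(runs, `[[`, numeric(n), "prob"))
  val_auc <- mean(vapply(runs, `[[`, numeric(1), "val_auc"))
  metrics <- if (length(te) > 0L) evaluate(prob[te], y[te]) else NULL
  structure(list(params = first$params, metrics = metrics,
                 val_auc = val_auc, best_epoch = first$best_epoch,
                 history = first$history, config = config, prob = prob),
            class = "hgnn_fit")
}

# forward pass reusing the precomputed first-layer aggregation G %*% x
forward_cached <- function(G, GX, params) {
  L <- length(params$W)
  a <- NULL
  for (l in seq_len(L)) {
    b <- if (l == 1L) GX else G %*% a
    z <- b %*% params$W[[l]] +
      matrix(params$b[[l]], nrow(b), length(params$b[[l]]), byrow = TRUE)
    a <- if (l < L) pmax(z, 0) else z
  }
  a
}

# one seeded optimization run against a precomputed operator
train_hgnn_once <- function(G, x, y, splits, config) {
  n <- nrow(x)
  tr <- splits$train; va <- splits$val
  L <- config$layers
  GX <- G %*% x
  params <- hgnn_init(ncol(x), config)
  Y <- cbind(1 - y, y)  # one-hot
  n_tr <- length(tr)
  # Adam state
  mW <- lapply(params$W, function(w) w * 0); vW <- mW
  mb <- lapply(params$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  p_drop <- config$dropout
  losses <- val_aucs <- rep(NA_real_, config$epochs)
  checkpoints <- vector("list", config$epochs)
  set.seed(config$seed + 1L)  # dropout stream (init used config$seed)
  for (epoch in seq_len(config$epochs)) {
    # forward with dropout on hidden activations
    a <- list(x)
    zz <- list(); bb <- list(); masks <- list()
    for (l in seq_len(L)) {
      bb[[l]] <- if (l == 1L) GX else G %*% a[[l]]
      z <- bb[[l]] %*% params$W[[l]] +
        matrix(params$b[[l]], n, length(params$b[[l]]), byrow = TRUE)
      zz[[l]] <- z
      if (l < L) {
        h <- pmax(z, 0)
        if (p_drop > 0) {
          masks[[l]] <- matrix(stats::rbinom(length(h), 1, 1 - p_drop),
                               nrow(h), ncol(h)) / (1 - p_drop)
          h <- h * masks[[l]]
        }
        a[[l + 1L]] <- h
      }
    }
    scores <- zz[[L]]
    P <- softmax_rows(scores)
    loss <- -mean(log(pmax(P[cbind(tr, y[tr] + 1L)], 1e-12)))
    # backward (cross-entropy on train rows only; G is symmetric)
    dZ <- matrix(0, n, 2)
    dZ[tr, ] <- (P[tr, , drop = FALSE] - Y[tr, , drop = FALSE]) / n_tr
    for (l in rev(seq_len(L))) {
      dW <- crossprod(bb[[l]], dZ) + config$weight_decay * params$W[[l]]
      db <- colSums(dZ)
      if (l > 1L) {
        dA <- G %*% tcrossprod(dZ, params$W[[l]])
        if (p_drop > 0) dA <- dA * masks[[l - 1L]]
        dZ <- dA * (zz[[l - 1L]] > 0)
      }
      t_adam <- epoch
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * dW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * dW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * db
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * db^2
      params$W[[l]] <- params$W[[l]] - lr * (mW[[l]] / (1 - beta1^t_adam)) /
        (sqrt(vW[[l]] / (1 - beta2^t_adam)) + eps)
      params$b[[l]] <- params$b[[l]] - lr * (mb[[l]] / (1 - beta1^t_adam)) /
        (sqrt(vb[[l]] / (1 - beta2^t_adam)) + eps)
    }
    # validation monitoring without dropout
    val_scores <- forward_cached(G, GX, params)
    losses[epoch] <- loss
    val_aucs[epoch] <- if (length(va) > 0L && length(unique(y[va])) > 1L)
      auc_score(val_scores[va, 2] - val_scores[va, 1], y[va])
    else NA_real_
    checkpoints[[epoch]] <- params
  }
  history <- data.frame(epoch = seq_len(config$epochs), loss = losses,
                        val_auc = val_aucs)
  if (all(is.na(val_aucs))) {
    best_params <- params; best_epoch <- config$epochs
    best_auc <- NA_real_
  } else {
    # the selection criterion is a moving average of the validation AUC,
    # restricted to epochs past the optimization transient: a single lucky
    # epoch on a small validation set (or a half-trained checkpoint) should
    # not win over a consistently good region of the trajectory
    win <- min(9L, config$epochs)
    sm <- stats::filter(val_aucs, rep(1 / win, win), sides = 2)
    sm[is.na(sm)] <- val_aucs[is.na(sm)]  # edges fall back to the raw curve
    burn_in <- max(1L, floor(config$epochs / 4))
    eligible <- burn_in:config$epochs
    best_epoch <- eligible[which.max(sm[eligible])]
    best_params <- checkpoints[[best_epoch]]
    best_auc <- val_aucs[best_epoch]
  }
  ens_epochs <- intersect(best_epoch + (-4:4), seq_len(config$epochs))
  # checkpoint ensemble: averaging class probabilities over the epochs
  # around the selected one damps single-checkpoint noise
  prob <- rowMeans(vapply(ens_epochs, function(e)
    softmax_rows(forward_cached(G, GX, checkpoints[[e]]))[, 2],
    numeric(n)))
  list(params = best_params, val_auc = best_auc, best_epoch = best_epoch,
       history = history, prob = prob)
}

#' @export
print.hgnn_fit <- function(x, ...) {
  cat(sprintf("<hgnn_fit> best epoch %d (val AUC %.3f)", x$best_epoch,
              x$val_auc))
  if (!is.null(x$metrics))
    cat(sprintf("; test AUC %.3f, sens %.3f, spec %.3f",
                x$metrics$auc, x$metrics$sensitivity,
                x$metrics$specificity))
  cat("\n")
  invisible(x)
}

#' Select the hyperedge size k by validation AUC
#'
#' Rebuilds the feature hypergraph for each k in the grid, trains the HGNN
#' and records the best validation AUC; returns the k with the highest
#' validation AUC, breaking ties toward the smaller k.
#'
#' @param features data.frame of (standardized) feature columns used both
#'   to build hypergraphs and as node features.
#' @param labels,splits,config as in [train_hgnn()].
#' @param weights per-feature hyperedge weights (see [ridge_weights()]).
#' @param k_grid candidate hyperedge sizes (the standard sweep is 5..13).
#' @return list: `best_k`, `val_auc_by_k` (data.frame `k`, `val_auc`).
#' @export
tune_k <- function(features, labels, splits, config = hgnn_config(),
                   weights = NULL, k_grid = 5:13) {
  stopifnot(length(k_grid) >= 1L, all(k_grid >= 2L))
  k_grid <- sort(unique(as.integer(k_grid)))
  aucs <- vapply(k_grid, function(k) {
    hg <- build_feature_hypergraphs(features, k = k, weights = weights)
    cfg <- config; cfg$k <- as.integer(k)
    fit <- train_hgnn(hg, as.matrix(data.matrix(features)), labels,
                      splits, cfg)
    fit$val_auc
  }, numeric(1))
  best_k <- k_grid[which.max(aucs)]  # which.max takes the first (smallest k)
  list(best_k = as.integer(best_k),
       val_auc_by_k = data.frame(k = as.integer(k_grid), val_auc = aucs))
}
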