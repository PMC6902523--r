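# Weighted CART trees on numeric features, supporting gini (classification,
# binary y in {0,1}) and mse (regression) criteria.  Split search is
# vectorized per feature with cumulative sums over the sorted node sample.
# This is the base learner for the decision-tree, random-forest, AdaBoost and
# gradient-boosting classifiers; the environment ships no CART package, so
# the partitioning is implemented here and cross-checked in tests.

build_tree <- function(X, y, w = NULL, max_depth = 30L, min_split = 2L,
                       min_leaf = 1L, mtry = ncol(X), criterion = c("gini",
                                                                    "mse")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, nrow(X))
  nodes <- new.env(parent = emptyenv())
  nodes$list <- list()
  grow <- function(idx, depth) {
    id <- length(nodes$list) + 1L
    nodes$list[id] <- list(NULL)        # reserve slot (children come later)
    yi <- y[idx]; wi <- w[idx]
    value <- sum(wi * yi) / sum(wi)
    leaf <- list(leaf = TRUE, value = value, n = length(idx))
    pure <- length(unique(yi)) == 1L
    if (depth >= max_depth || length(idx) < min_split || pure) {
      nodes$list[[id]] <- leaf
      return(id)
    }
    sp <- best_split(X, y, w, idx, min_leaf, mtry, criterion)
    if (is.null(sp)) {
      nodes$list[[id]] <- leaf
      return(id)
    }
    left_idx <- idx[X[idx, sp$feature] <= sp$threshold]
    right_idx <- idx[X[idx, sp$feature] > sp$threshold]
    lid <- grow(left_idx, depth + 1L)
    rid <- grow(right_idx, depth + 1L)
    nodes$list[[id]] <- list(leaf = FALSE, feature = sp$feature,
                             threshold = sp$threshold, left = lid,
                             right = rid, value = value, n = length(idx))
    id
  }
  root <- grow(seq_len(nrow(X)), 0L)
  structure(list(nodes = nodes$list, root = root, criterion = criterion,
                 p = ncol(X)), class = "vhf_tree")
}

best_split <- function(X, y, w, idx, min_leaf, mtry, criterion) {
  p <- ncol(X)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  best <- NULL
  best_score <- Inf
  yi <- y[idx]; wi <- w[idx]
  W <- sum(wi)
  for (j in feats) {
    v <- X[idx, j]
    o <- order(v)
    vs <- v[o]; ys <- yi[o]; ws <- wi[o]
    nl <- length(vs)
    if (nl < 2L) next
    cut_ok <- which(vs[-nl] < vs[-1])    # split between distinct values
    cut_ok <- cut_ok[cut_ok >= min_leaf & (nl - cut_ok) >= min_leaf]
    if (!length(cut_ok)) next
    wl <- cumsum(ws)[cut_ok]
    wr <- W - wl
    if (criterion == "gini") {
      wyl <- cumsum(ws * ys)[cut_ok]
      wyr <- sum(ws * ys) - wyl
      pl <- wyl / wl; pr <- wyr / wr
      score <- (wl * 2 * pl * (1 - pl) + wr * 2 * pr * (1 - pr)) / W
    } else {
      wyl <- cumsum(ws * ys)[cut_ok]
      wy2l <- cumsum(ws * ys^2)[cut_ok]
      wyr <- sum(ws * ys) - wyl
      wy2r <- sum(ws * ys^2) - wy2l
      score <- ((wy2l - wyl^2 / wl) + (wy2r - wyr^2 / wr)) / W
    }
    b <- which.min(score)
    if (score[b] < best_score - 1e-12) {
      best_score <- score[b]
      best <- list(feature = j,
                   threshold = (vs[cut_ok[b]] + vs[cut_ok[b] + 1L]) / 2)
    }
  }
  best
}

# Predicted node values; leaf_id = TRUE additionally returns the terminal
# node index of every row (needed for the boosting Newton step).
predict_tree <- function(tree, X, leaf_id = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  out <- numeric(n)
  lid <- integer(n)
  descend <- function(node_id, rows) {
    node <- tree$nodes[[node_id]]
    if (node$leaf) {
      out[rows] <<- node$value
      lid[rows] <<- node_id
      return(invisible())
    }
    go_left <- X[rows, node$feature] <= node$threshold
    if (any(go_left)) descend(node$left, rows[go_left])
    if (any(!go_left)) descend(node$right, rows[!go_left])
  }
  descend(tree$root, seq_len(n))
  if (leaf_id) list(value = out, leaf = lid) else out
}

# Overwrite leaf values (boosting terminal-region updates).
set_leaf_values <- function(tree, values_by_leaf) {
  for (id in names(values_by_leaf))
    tree$nodes[[as.integer(id)]]$value <- values_by_leaf[[id]]
  tree
}
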