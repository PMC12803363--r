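## In-house learners ----------------------------------------------------------
##
## The environment this package targets ships no gradient-boosting or deep
## learning library, so both forecasting learners are implemented here at the
## small scale the feature tables require: `gbt_*` is gradient tree boosting
## for squared loss with L2 leaf regularization and early stopping (the
## XGBoost objective restricted to exact greedy splits), and `rnn_*` is a
## single-layer tanh recurrent network with static covariates concatenated at
## the readout, trained with Adam and early stopping.

## ---- gradient-boosted regression trees ------------------------------------

gbt_best_split <- function(x, g, min_node, lambda) {
  o <- order(x)
  xs <- x[o]; gs <- g[o]
  n <- length(x)
  cg <- cumsum(gs)
  total <- cg[n]
  pos <- which(diff(xs) > 0)
  pos <- pos[pos >= min_node & (n - pos) >= min_node]
  if (!length(pos)) return(NULL)
  gl <- cg[pos]; gr <- total - gl
  gain <- gl^2 / (pos + lambda) + gr^2 / (n - pos + lambda) -
    total^2 / (n + lambda)
  b <- which.max(gain)
  list(gain = gain[b], threshold = (xs[pos[b]] + xs[pos[b] + 1L]) / 2)
}

gbt_build_tree <- function(X, g, max_depth, min_node, lambda) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  build <- function(idx, depth) {
    id <- new_node()
    nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         value = sum(g[idx]) / (length(idx) + lambda))
    if (depth >= max_depth || length(idx) < 2L * min_node) return(id)
    best <- NULL; best_j <- NA_integer_
    for (j in seq_len(ncol(X))) {
      s <- gbt_best_split(X[idx, j], g[idx], min_node, lambda)
      if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
        best <- s; best_j <- j
      }
    }
    if (is.null(best) || best$gain <= 1e-12) return(id)
    go_left <- X[idx, best_j] < best$threshold
    l <- build(idx[go_left], depth + 1L)
    r <- build(idx[!go_left], depth + 1L)
    nodes[[id]]$feature <<- best_j
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$left <<- l
    nodes[[id]]$right <<- r
    id
  }
  build(seq_along(g), 0L)
  nodes
}

gbt_tree_predict <- function(nodes, X) {
  out <- numeric(nrow(X))
  walk <- function(id, idx) {
    nd <- nodes[[id]]
    if (is.na(nd$feature)) {
      out[idx] <<- nd$value
      return(invisible())
    }
    go_left <- X[idx, nd$feature] < nd$threshold
    if (any(go_left)) walk(nd$left, idx[go_left])
    if (any(!go_left)) walk(nd$right, idx[!go_left])
  }
  if (nrow(X)) walk(1L, seq_len(nrow(X)))
  out
}

gbt_train <- function(X, y, nrounds = 500L, eta = 0.05, max_depth = 4L,
                      min_node = 10L, lambda = 1, subsample = 1,
                      val_fraction = 0.1, patience = 25L, val_idx = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stop_if(n == 0L, "empty training data")
  stop_if(anyNA(X) || anyNA(y), "NaN/NA features or targets")
  min_node <- max(1L, min(min_node, floor(n / 4)))
  val <- if (!is.null(val_idx)) val_idx
  else if (val_fraction > 0 && n >= 20L)
    sample(n, max(2L, floor(val_fraction * n))) else integer(0)
  tr <- setdiff(seq_len(n), val)
  base <- mean(y[tr])
  pred <- rep(base, n)
  trees <- vector("list", nrounds)
  best_err <- Inf; best_iter <- 0L; stale <- 0L
  for (it in seq_len(nrounds)) {
    rows <- if (subsample < 1) sample(tr, ceiling(subsample * length(tr))) else tr
    g <- y[rows] - pred[rows]
    nodes <- gbt_build_tree(X[rows, , drop = FALSE], g, max_depth, min_node, lambda)
    trees[[it]] <- nodes
    pred <- pred + eta * gbt_tree_predict(nodes, X)
    if (length(val)) {
      err <- mean((y[val] - pred[val])^2)
      if (err < best_err - 1e-10) {
        best_err <- err; best_iter <- it; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    } else best_iter <- it
  }
  list(kind = "gbt", base = base, eta = eta,
       trees = trees[seq_len(if (best_iter > 0L) best_iter else 1L)])
}

gbt_predict <- function(model, X, trees = NULL) {
  X <- as.matrix(X)
  use <- model$trees
  if (!is.null(trees)) use <- use[trees]
  out <- rep(model$base, nrow(X))
  for (nodes in use) out <- out + model$eta * gbt_tree_predict(nodes, X)
  out
}

## ---- single-layer tanh recurrent network ----------------------------------
##
## h_t = tanh(wx * x_t + U h_{t-1} + b);  yhat = h_L v + C u + c0.
## S: n x L sequence matrix (scalar input per step), C: n x q statics.

rnn_init <- function(hidden, q, y) {
  list(wx = rnorm(hidden, 0, 0.3),
       U = matrix(rnorm(hidden * hidden, 0, 0.3 / sqrt(hidden)), hidden),
       b = numeric(hidden),
       v = rnorm(hidden, 0, 0.3 / sqrt(hidden)),
       u = numeric(q),
       c0 = mean(y))
}

rnn_forward <- function(p, S, C) {
  n <- nrow(S); L <- ncol(S); H <- length(p$wx)
  Hs <- vector("list", L)
  h <- matrix(0, n, H)
  for (t in seq_len(L)) {
    h <- tanh(outer(S[, t], p$wx) + h %*% p$U +
                matrix(p$b, n, H, byrow = TRUE))
    Hs[[t]] <- h
  }
  yhat <- drop(h %*% p$v) + p$c0
  if (ncol(C)) yhat <- yhat + drop(C %*% p$u)
  list(yhat = yhat, Hs = Hs)
}

rnn_grad <- function(p, S, C, y) {
  n <- nrow(S); L <- ncol(S)
  fw <- rnn_forward(p, S, C)
  dpred <- 2 * (fw$yhat - y) / n
  hL <- fw$Hs[[L]]
  g <- list(wx = 0 * p$wx, U = 0 * p$U, b = 0 * p$b,
            v = drop(crossprod(hL, dpred)),
            u = if (ncol(C)) drop(crossprod(C, dpred)) else numeric(0),
            c0 = sum(dpred))
  dH <- dpred %o% p$v
  for (t in L:1) {
    Ht <- fw$Hs[[t]]
    dA <- dH * (1 - Ht^2)
    g$wx <- g$wx + drop(crossprod(dA, S[, t]))
    g$b <- g$b + colSums(dA)
    Hprev <- if (t > 1L) fw$Hs[[t - 1L]] else matrix(0, n, length(p$wx))
    g$U <- g$U + crossprod(Hprev, dA)
    dH <- dA %*% t(p$U)
  }
  list(grad = g, mse = mean((fw$yhat - y)^2))
}

rnn_train <- function(S, C, y, hidden = 32L, epochs = 300L, lr = 0.01,
                      val_idx = integer(0), patience = 25L, l2 = 1e-5) {
  S <- as.matrix(S); C <- as.matrix(C)
  stop_if(nrow(S) == 0L, "empty training data")
  stop_if(anyNA(S) || anyNA(C) || anyNA(y), "NaN/NA features or targets")
  tr <- setdiff(seq_len(nrow(S)), val_idx)
  p <- rnn_init(hidden, ncol(C), y[tr])
  mom1 <- mom2 <- rapply(p, function(x) 0 * x, how = "replace")
  b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
  best <- p; best_err <- Inf; stale <- 0L
  for (ep in seq_len(epochs)) {
    gr <- rnn_grad(p, S[tr, , drop = FALSE], C[tr, , drop = FALSE], y[tr])
    for (nm in names(p)) {
      gnm <- gr$grad[[nm]] + l2 * p[[nm]]
      mom1[[nm]] <- b1 * mom1[[nm]] + (1 - b1) * gnm
      mom2[[nm]] <- b2 * mom2[[nm]] + (1 - b2) * gnm^2
      m_hat <- mom1[[nm]] / (1 - b1^ep)
      v_hat <- mom2[[nm]] / (1 - b2^ep)
      p[[nm]] <- p[[nm]] - lr * m_hat / (sqrt(v_hat) + epsl)
    }
    err <- if (length(val_idx))
      mean((rnn_forward(p, S[val_idx, , drop = FALSE],
                        C[val_idx, , drop = FALSE])$yhat - y[val_idx])^2)
    else gr$mse
    if (err < best_err - 1e-10) {
      best <- p; best_err <- err; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  list(kind = "rnn", params = best)
}

rnn_predict <- function(model, S, C) {
  rnn_forward(model$params, as.matrix(S), as.matrix(C))$yhat
}
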