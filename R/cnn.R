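# A four-block residual 1D convolutional network for force time-series
# classification, implemented in vectorised base R. Convolutions use an
# im2col gather followed by a single BLAS matrix multiplication per layer
# and batch; backpropagation is analytic and verified against
# finite-difference gradients in the test suite.
#
# Architecture per block: conv(k) -> ReLU -> conv(k), plus an identity (or
# width-1 projection) shortcut, ReLU after the add, then max-pooling of
# width/stride 2. Head: global average pooling -> dropout -> dense softmax
# over the four treatment classes.

#' Specify a 1D residual CNN
#'
#' The default mirrors the study architecture's shape — four convolutional
#' blocks with increasing filter counts, shortcuts, max-pooling after every
#' block, global average pooling and a four-way softmax head — with the
#' unprinted hyperparameters (filter schedule 64/128/256/512, kernel 9, two
#' convolutions per block, dropout 0.5, Adam at 1e-3, batch 64) exposed
#' here. Use [cnn_count_params()] to compare a configuration's trainable
#' parameter count with a reference figure.
#'
#' @param input_len segment length in samples (default 1000).
#' @param n_channels input channels (default 3: force X, Y, Z).
#' @param filters filter counts per block; should increase block to block
#'   (a warning is issued otherwise).
#' @param kernel convolution kernel size (odd).
#' @param n_classes output classes (default 4).
#' @param dropout dropout rate before the dense layer.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @return A list of class `cnn_spec`.
#' @export
cnn_spec <- function(input_len = 1000L, n_channels = 3L,
                     filters = c(64L, 128L, 256L, 512L), kernel = 9L,
                     n_classes = 4L, dropout = 0.5, lr = 1e-3,
                     batch_size = 64L) {
  if (kernel %% 2L == 0L) stop_domain("kernel size must be odd")
  if (any(diff(filters) <= 0))
    warning("filter schedule is not strictly increasing", call. = FALSE)
  if (input_len %/% 2L^length(filters) < 2L)
    stop_domain("input_len too short for ", length(filters), " pooling stages")
  structure(list(input_len = as.integer(input_len),
                 n_channels = as.integer(n_channels),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 lr = lr, batch_size = as.integer(batch_size)),
            class = "cnn_spec")
}

#' Trainable parameter count of a CNN specification
#'
#' Closed-form count: each block has two convolutions
#' (`k * C_in * F + F` and `k * F * F + F`) plus a width-1 projection
#' shortcut (`C_in * F + F`) when the channel count changes; the head adds
#' `F_last * n_classes + n_classes`.
#'
#' @param spec a [cnn_spec()].
#' @return Integer parameter count.
#' @export
cnn_count_params <- function(spec) {
  cin <- spec$n_channels
  k <- spec$kernel
  total <- 0
  for (f in spec$filters) {
    total <- total + (k * cin * f + f) + (k * f * f + f)
    if (cin != f) total <- total + (cin * f + f)
    cin <- f
  }
  total + cin * spec$n_classes + spec$n_classes
}

# ---- parameter initialisation (He-normal for convolutions) ----

cnn_init <- function(spec, seed = NULL) {
  with_seed(seed, {
    params <- list()
    cin <- spec$n_channels
    k <- spec$kernel
    for (b in seq_along(spec$filters)) {
      f <- spec$filters[b]
      params[[paste0("W1_", b)]] <- matrix(
        stats::rnorm(k * cin * f, 0, sqrt(2 / (k * cin))), k * cin, f)
      params[[paste0("b1_", b)]] <- numeric(f)
      params[[paste0("W2_", b)]] <- matrix(
        stats::rnorm(k * f * f, 0, sqrt(2 / (k * f))), k * f, f)
      params[[paste0("b2_", b)]] <- numeric(f)
      if (cin != f) {
        params[[paste0("Wp_", b)]] <- matrix(
          stats::rnorm(cin * f, 0, sqrt(2 / cin)), cin, f)
        params[[paste0("bp_", b)]] <- numeric(f)
      }
      cin <- f
    }
    params$Wd <- matrix(stats::rnorm(cin * spec$n_classes, 0, sqrt(1 / cin)),
                        cin, spec$n_classes)
    params$bd <- numeric(spec$n_classes)
    params
  })
}

# ---- primitive layers on sample-major (B*T) x C matrices ----

.idx_cache <- new.env(parent = emptyenv())

# Row-index matrix for the im2col gather: entry [i, s] is the padded-input
# row feeding offset s at output row i; out-of-range taps hit the zero row.
# Memoised per (B, T, k) since the same geometry recurs every batch.
conv_idx <- function(B, T, k) {
  key <- paste(B, T, k, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- conv_idx_build(B, T, k)
  if (length(ls(.idx_cache)) > 32L) rm(list = ls(.idx_cache), envir = .idx_cache)
  .idx_cache[[key]] <- val
  val
}

conv_idx_build <- function(B, T, k) {
  off <- seq_len(k) - (k %/% 2L + 1L)
  base <- matrix(rep(seq_len(T), k) + rep(off, each = T), T, k)
  base[base < 1L | base > T] <- NA_integer_
  idx <- base[rep(seq_len(T), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * T, each = T)
  idx[is.na(idx)] <- B * T + 1L
  idx
}

im2col <- function(X, idx, k, cin) {
  Xp <- rbind(X, 0)
  out <- matrix(0, nrow(X), k * cin)
  for (s in seq_len(k))
    out[, ((s - 1L) * cin + 1L):(s * cin)] <- Xp[idx[, s], , drop = FALSE]
  out
}

col2im <- function(dXcol, idx, k, cin, n) {
  dXp <- matrix(0, n + 1L, cin)
  for (s in seq_len(k)) {
    tgt <- idx[, s]
    ok <- tgt <= n
    cols <- ((s - 1L) * cin + 1L):(s * cin)
    dXp[tgt[ok], ] <- dXp[tgt[ok], , drop = FALSE] +
      dXcol[ok, cols, drop = FALSE]
  }
  dXp[seq_len(n), , drop = FALSE]
}

add_bias <- function(Y, b) Y + matrix(b, nrow(Y), length(b), byrow = TRUE)

# Max-pooling of width/stride 2 floors the length; a trailing odd sample
# is dropped (and receives zero gradient), as in standard pooling layers.
pool_idx <- function(B, T) as.vector(outer(seq(1L, 2L * (T %/% 2L), 2L),
                                           (seq_len(B) - 1L) * T, "+"))

# ---- forward pass (caches kept for backprop when train = TRUE) ----

cnn_forward <- function(params, spec, X, B, train = FALSE, drop_mask = NULL) {
  T <- spec$input_len
  cin <- spec$n_channels
  k <- spec$kernel
  cache <- list()
  A <- X
  for (b in seq_along(spec$filters)) {
    f <- spec$filters[b]
    idx <- conv_idx(B, T, k)
    Xc1 <- im2col(A, idx, k, cin)
    Z1 <- add_bias(Xc1 %*% params[[paste0("W1_", b)]],
                   params[[paste0("b1_", b)]])
    A1 <- pmax(Z1, 0)
    Xc2 <- im2col(A1, idx, k, f)
    Z2 <- add_bias(Xc2 %*% params[[paste0("W2_", b)]],
                   params[[paste0("b2_", b)]])
    S <- if (cin != f)
      add_bias(A %*% params[[paste0("Wp_", b)]], params[[paste0("bp_", b)]])
    else A
    R <- pmax(Z2 + S, 0)
    pidx <- pool_idx(B, T)
    Ro <- R[pidx, , drop = FALSE]
    Re <- R[pidx + 1L, , drop = FALSE]
    mask <- Ro >= Re
    P <- mask * Ro + (!mask) * Re
    if (train)
      cache[[b]] <- list(A = A, idx = idx, Xc1 = Xc1, Z1 = Z1, A1 = A1,
                         Xc2 = Xc2, Z2 = Z2, S = S, R = R, pidx = pidx,
                         mask = mask, T = T, cin = cin)
    A <- P
    T <- T %/% 2L
    cin <- f
  }
  grp <- rep(seq_len(B), each = T)
  G <- rowsum(A, grp) / T
  Gd <- if (train && !is.null(drop_mask)) G * drop_mask else G
  Z <- add_bias(Gd %*% params$Wd, params$bd)
  Zs <- Z - apply(Z, 1, max)
  P <- exp(Zs)
  P <- P / rowSums(P)
  list(probs = P, logits = Z, G = G, Gd = Gd, cache = cache,
       T_out = T, grp = grp)
}

# ---- combined forward + backward, returning loss and gradients ----

cnn_grads <- function(params, spec, X, y, B, drop_mask = NULL) {
  fw <- cnn_forward(params, spec, X, B, train = TRUE, drop_mask = drop_mask)
  P <- fw$probs
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(B), y + 1L)] + eps))
  grads <- list()
  dZ <- P
  dZ[cbind(seq_len(B), y + 1L)] <- dZ[cbind(seq_len(B), y + 1L)] - 1
  dZ <- dZ / B
  grads$Wd <- crossprod(fw$Gd, dZ)
  grads$bd <- colSums(dZ)
  dG <- tcrossprod(dZ, params$Wd)
  if (!is.null(drop_mask)) dG <- dG * drop_mask
  dA <- dG[fw$grp, , drop = FALSE] / fw$T_out
  k <- spec$kernel
  for (b in rev(seq_along(spec$filters))) {
    cc <- fw$cache[[b]]
    f <- spec$filters[b]
    # un-pool
    dR <- matrix(0, nrow(cc$R), ncol(cc$R))
    dR[cc$pidx, ] <- dA * cc$mask
    dR[cc$pidx + 1L, ] <- dR[cc$pidx + 1L, , drop = FALSE] + dA * (!cc$mask)
    # ReLU after the residual add
    dR <- dR * (cc$R > 0)
    # main branch: conv2
    grads[[paste0("W2_", b)]] <- crossprod(cc$Xc2, dR)
    grads[[paste0("b2_", b)]] <- colSums(dR)
    dA1 <- col2im(tcrossprod(dR, params[[paste0("W2_", b)]]),
                  cc$idx, k, f, nrow(cc$A1))
    dA1 <- dA1 * (cc$Z1 > 0)
    grads[[paste0("W1_", b)]] <- crossprod(cc$Xc1, dA1)
    grads[[paste0("b1_", b)]] <- colSums(dA1)
    if (cc$cin != f) {
      grads[[paste0("Wp_", b)]] <- crossprod(cc$A, dR)
      grads[[paste0("bp_", b)]] <- colSums(dR)
    }
    if (b > 1L) {  # the gradient w.r.t. the network input is never used
      dA_main <- col2im(tcrossprod(dA1, params[[paste0("W1_", b)]]),
                        cc$idx, k, cc$cin, nrow(cc$A))
      dA_short <- if (cc$cin != f)
        tcrossprod(dR, params[[paste0("Wp_", b)]]) else dR
      dA <- dA_main + dA_short
    }
  }
  list(loss = loss, grads = grads, probs = P)
}

# ---- Adam optimiser ----

adam_step <- function(state, params, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * (state$m[[nm]] %||% (g * 0)) + (1 - beta1) * g
    state$v[[nm]] <- beta2 * (state$v[[nm]] %||% (g * 0)) + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = state, params = params)
}

# Gather a batch of segments (sample-major rows) from a dataset matrix.
batch_rows <- function(idx, seg_len)
  rep((idx - 1L) * seg_len, each = seg_len) + seq_len(seg_len)

#' Train the CNN on a segment dataset
#'
#' Minimises categorical cross-entropy with Adam over shuffled minibatches.
#' Channels are standardised to zero mean and unit variance using the
#' training data (the statistics are stored in the model and re-applied at
#' prediction time). Deterministic for a fixed seed under single-threaded
#' numerics. Training aborts with diagnostics if the loss becomes
#' non-finite.
#'
#' @param spec a [cnn_spec()]; its `input_len`/`n_channels` must match the
#'   dataset.
#' @param train_set a `segment_dataset` (see [build_dataset()],
#'   [dataset_subset()]).
#' @param epochs training epochs (study setting: 100).
#' @param seed seed for initialisation, shuffling and dropout.
#' @param verbose print per-epoch loss.
#' @return A list of class `benthoforce_cnn`: parameters, spec,
#'   standardisation stats, and `history` (`data.frame` epoch/loss/accuracy).
#' @export
cnn_train <- function(spec, train_set, epochs = 100L, seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(train_set, "segment_dataset"))
  if (train_set$seg_len != spec$input_len ||
      train_set$n_channels != spec$n_channels)
    stop_domain("spec input shape does not match the dataset")
  n <- nrow(train_set$meta)
  if (n == 0L) stop_domain("empty training set")
  mu <- colMeans(train_set$x)
  sdv <- apply(train_set$x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xall <- sweep(sweep(train_set$x, 2, mu), 2, sdv, "/")
  y <- train_set$meta$label
  with_seed(seed, {
    params <- cnn_init(spec, seed = NULL)
    state <- list(m = list(), v = list())
    t_step <- 0L
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          accuracy = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      correct <- 0L
      for (start in seq(1L, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1L, n)]
        B <- length(idx)
        Xb <- Xall[batch_rows(idx, spec$input_len), , drop = FALSE]
        yb <- y[idx]
        drop_mask <- if (spec$dropout > 0)
          matrix((stats::runif(B * spec$filters[length(spec$filters)]) >
                    spec$dropout) / (1 - spec$dropout),
                 B, spec$filters[length(spec$filters)])
        else NULL
        gr <- cnn_grads(params, spec, Xb, yb, B, drop_mask)
        if (!is.finite(gr$loss))
          stop_domain("training diverged: non-finite loss at epoch ", ep)
        t_step <- t_step + 1L
        upd <- adam_step(state, params, gr$grads, spec$lr, t_step)
        state <- upd$state
        params <- upd$params
        losses <- c(losses, gr$loss * B)
        correct <- correct + sum(max.col(gr$probs, ties.method = "first") -
                                   1L == yb)
      }
      history <- rbind(history, data.frame(epoch = ep, loss = sum(losses) / n,
                                           accuracy = correct / n))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        sum(losses) / n, correct / n))
    }
    structure(list(params = params, spec = spec, mu = mu, sd = sdv,
                   history = history, n_train = n,
                   n_params = cnn_count_params(spec)),
              class = "benthoforce_cnn")
  })
}

#' @export
print.benthoforce_cnn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("<benthoforce_cnn> %d blocks (filters %s), %s trainable",
                     " parameters\n  trained %d epochs on %d segments;",
                     " final loss %.4f, accuracy %.3f\n"),
              length(x$spec$filters),
              paste(x$spec$filters, collapse = "/"),
              format(x$n_params, big.mark = ","),
              nrow(x$history), x$n_train, last$loss, last$accuracy))
  invisible(x)
}

#' Predict treatment classes or probabilities for segments
#'
#' @param object a trained `benthoforce_cnn`.
#' @param ds a `segment_dataset`.
#' @param type `"class"` for integer labels (0..3) or `"prob"` for the
#'   softmax matrix.
#' @param batch_size evaluation batch size.
#' @param ... unused.
#' @return Integer labels or a probability matrix.
#' @export
predict.benthoforce_cnn <- function(object, ds, type = c("class", "prob"),
                                    batch_size = 256L, ...) {
  type <- match.arg(type)
  stopifnot(inherits(ds, "segment_dataset"))
  n <- nrow(ds$meta)
  X <- sweep(sweep(ds$x, 2, object$mu), 2, object$sd, "/")
  probs <- matrix(0, n, object$spec$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- cnn_forward(object$params, object$spec,
                      X[batch_rows(idx, object$spec$input_len), , drop = FALSE],
                      length(idx), train = FALSE)
    probs[idx, ] <- fw$probs
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' Confusion matrix (rows observed, columns predicted)
#'
#' @param observed,predicted integer labels 0..(n_classes-1).
#' @param n_classes number of classes.
#' @param class_names optional dimnames (default CS/CR/BR/BS order of the
#'   integer coding).
#' @return `n_classes x n_classes` count matrix.
#' @export
confusion_matrix <- function(observed, predicted, n_classes = 4L,
                             class_names = names(sort(TREATMENT_LABELS))) {
  if (length(observed) != length(predicted))
    stop_domain("observed and predicted lengths differ")
  if (any(!observed %in% 0:(n_classes - 1L)) ||
      any(!predicted %in% 0:(n_classes - 1L)))
    stop_domain("labels outside 0..", n_classes - 1L)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(observed = class_names,
                               predicted = class_names))
  for (i in seq_along(observed))
    cm[observed[i] + 1L, predicted[i] + 1L] <-
      cm[observed[i] + 1L, predicted[i] + 1L] + 1L
  cm
}

#' Per-class accuracy (precision), recall and F1 from a confusion matrix
#'
#' The per-class model accuracy is
#' `Ac_a = Cpred_a / (Cpred_a + Fpred_b + Fpred_c + Fpred_d)`: correct
#' predictions of class a over all predictions assigned to class a — i.e.
#' the precision of class a. Recall (diagonal over row sum) is reported for
#' transparency, and F1 is the harmonic mean of the two.
#'
#' @param confusion count matrix, rows observed, columns predicted.
#' @return A list of class `class_metrics`: `confusion`, `Ac` (precision),
#'   `recall`, `F1` (all per class), `overall_accuracy`.
#' @export
class_metrics <- function(confusion) {
  if (any(confusion < 0)) stop_domain("negative confusion counts")
  d <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, d / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, d / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(confusion = confusion, Ac = prec, recall = rec, F1 = f1,
                 overall_accuracy = sum(d) / sum(confusion)),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("Confusion matrix (rows observed, columns predicted):\n")
  print(x$confusion)
  tab <- rbind(Ac = x$Ac, recall = x$recall, F1 = x$F1)
  print(round(tab, 3))
  cat(sprintf("Overall accuracy: %.3f\n", x$overall_accuracy))
  invisible(x)
}

#' Evaluate a trained CNN on a validation set
#'
#' @param model a `benthoforce_cnn`.
#' @param val_set a `segment_dataset`.
#' @return A [class_metrics()] object.
#' @export
cnn_evaluate <- function(model, val_set) {
  pred <- stats::predict(model, val_set, type = "class")
  class_metrics(confusion_matrix(val_set$meta$label, pred,
                                 model$spec$n_classes))
}

#' k-fold cross-validation of the CNN
#'
#' For each fold, trains on the remaining folds and evaluates on the
#' held-out fold, so every segment is validated exactly once; per-class F1
#' is then averaged across the fold models (the study's summary statistic,
#' e.g. "mean F1 = 0.88" for CS).
#'
#' @param ds a fold-assigned `segment_dataset`.
#' @param spec a [cnn_spec()].
#' @param epochs training epochs per fold.
#' @param seed base seed; fold f trains with `seed + f`.
#' @param verbose print progress.
#' @return list of class `cnn_cv`: `metrics` (per-fold [class_metrics()]),
#'   `mean_F1` (per class), `sd_F1`, `folds`.
#' @export
cross_validate <- function(ds, spec, epochs = 100L, seed = 1L,
                           verbose = FALSE) {
  folds <- sort(unique(ds$meta$fold))
  metrics <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[i]
    tr <- dataset_subset(ds, which(ds$meta$fold != f))
    va <- dataset_subset(ds, which(ds$meta$fold == f))
    if (verbose)
      message(sprintf("fold %d: training on %d, validating on %d segments",
                      f, nrow(tr$meta), nrow(va$meta)))
    model <- cnn_train(spec, tr, epochs = epochs, seed = seed + f,
                       verbose = verbose)
    metrics[[i]] <- cnn_evaluate(model, va)
  }
  f1 <- vapply(metrics, function(mm) mm$F1, numeric(spec$n_classes))
  structure(list(metrics = metrics,
                 mean_F1 = rowMeans(f1),
                 sd_F1 = apply(f1, 1, stats::sd),
                 folds = folds),
            class = "cnn_cv")
}

#' @export
print.cnn_cv <- function(x, ...) {
  cat(sprintf("<cnn_cv> %d folds\n", length(x$folds)))
  tab <- rbind(`mean F1` = x$mean_F1, `s.d.` = x$sd_F1)
  print(round(tab, 3))
  invisible(x)
}
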