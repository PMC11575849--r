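test_that("parameter count matches a layer-by-layer arithmetic oracle", {
  for (spec in list(cnn_spec(input_len = 64L, n_channels = 3L,
                             filters = c(4L, 8L), kernel = 3L),
                    reduced_cnn_spec())) {
    params <- benthoforce:::cnn_init(spec, seed = 1)
    expect_equal(cnn_count_params(spec), sum(lengths(params)))
    # independent arithmetic oracle
    cin <- spec$n_channels; k <- spec$kernel; total <- 0
    for (f in spec$filters) {
      total <- total + k * cin * f + f + k * f * f + f
      if (cin != f) total <- total + cin * f + f
      cin <- f
    }
    total <- total + cin * spec$n_classes + spec$n_classes
    expect_equal(cnn_count_params(spec), total)
  }
  # the default mirrors the study shape: 4 blocks, increasing filters,
  # softmax width 4, parameter count in the millions
  def <- cnn_spec()
  expect_length(def$filters, 4L)
  expect_true(all(diff(def$filters) > 0))
  expect_equal(def$n_classes, 4L)
  expect_gt(cnn_count_params(def), 1e6)
  expect_warning(cnn_spec(input_len = 64L, filters = c(8L, 8L)),
                 "not strictly increasing")
})

test_that("backpropagation matches finite-difference gradients", {
  spec <- cnn_spec(input_len = 22L, n_channels = 2L, filters = c(3L, 5L),
                   kernel = 3L, n_classes = 3L, dropout = 0)
  params <- benthoforce:::cnn_init(spec, seed = 1)
  set.seed(1)
  B <- 4L
  X <- matrix(rnorm(B * 22 * 2), B * 22, 2)
  y <- c(0L, 1L, 2L, 1L)
  gr <- benthoforce:::cnn_grads(params, spec, X, y, B)
  numgrad <- function(nm, i, eps = 1e-5) {
    p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
    (benthoforce:::cnn_grads(p1, spec, X, y, B)$loss -
       benthoforce:::cnn_grads(p2, spec, X, y, B)$loss) / (2 * eps)
  }
  set.seed(7)
  for (nm in names(gr$grads)) {
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      a <- gr$grads[[nm]][i]
      b <- numgrad(nm, i)
      expect_lt(abs(a - b) / max(1e-6, abs(a) + abs(b)), 1e-5)
    }
  }
})

test_that("zero-weight conv blocks with matching channels act as identity", {
  spec <- suppressWarnings(  # constant filter schedule is intentional here
    cnn_spec(input_len = 16L, n_channels = 4L, filters = c(4L, 4L),
             kernel = 3L, dropout = 0))
  params <- benthoforce:::cnn_init(spec, seed = 2)
  expect_false(any(grepl("^Wp_", names(params))))  # identity shortcuts
  for (nm in grep("^(W1|W2|b1|b2)_", names(params), value = TRUE))
    params[[nm]][] <- 0
  params$Wd[] <- diag(4)
  params$bd[] <- 0
  set.seed(3)
  B <- 2L
  X <- matrix(abs(rnorm(B * 16 * 4)), B * 16, 4)  # non-negative input
  fw <- benthoforce:::cnn_forward(params, spec, X, B)
  # manual reference: two max-pools then GAP on the untouched input
  manual <- t(sapply(seq_len(B), function(s) {
    xb <- X[((s - 1) * 16 + 1):(s * 16), ]
    p1 <- pmax(xb[seq(1, 15, 2), ], xb[seq(2, 16, 2), ])
    p2 <- pmax(p1[c(1, 3, 5, 7), ], p1[c(2, 4, 6, 8), ])
    colMeans(p2)
  }))
  expect_equal(fw$G, manual, ignore_attr = TRUE)
})

test_that("training learns a separable two-tone task and records history", {
  set.seed(4)
  n <- 96L
  len <- 128L
  tt <- (0:(len - 1)) / 100
  x <- matrix(0, n * len, 1)
  y <- rep(0:1, each = n / 2)
  for (i in seq_len(n)) {
    f0 <- if (y[i] == 0L) 5 else 12
    x[((i - 1) * len + 1):(i * len), 1] <-
      sin(2 * pi * f0 * tt + runif(1, 0, 6)) + rnorm(len, 0, 0.3)
  }
  ds <- structure(list(x = x, meta = data.frame(label = y), seg_len = len,
                       n_channels = 1L), class = "segment_dataset")
  spec <- cnn_spec(input_len = len, n_channels = 1L, filters = c(4L, 8L),
                   kernel = 5L, n_classes = 2L, dropout = 0,
                   batch_size = 32L)
  m <- cnn_train(spec, ds, epochs = 20L, seed = 5)
  expect_equal(nrow(m$history), 20L)
  expect_gt(m$history$accuracy[20], 0.95)
  # optimisation sanity: epoch-wise moving average of the loss decreases
  ma <- stats::filter(m$history$loss, rep(1 / 5, 5), sides = 1)
  expect_lt(ma[20], ma[10])
  # determinism under a fixed seed
  m2 <- cnn_train(spec, ds, epochs = 2L, seed = 9)
  m3 <- cnn_train(spec, ds, epochs = 2L, seed = 9)
  expect_identical(m2$params, m3$params)
  expect_identical(m2$history, m3$history)
  expect_identical(predict(m2, ds), predict(m3, ds))
})

test_that("evaluation implements the printed per-class accuracy and F1", {
  # perfect predictor
  obs <- rep(0:3, each = 10)
  pm <- class_metrics(confusion_matrix(obs, obs))
  expect_equal(unname(pm$Ac), rep(1, 4))
  expect_equal(unname(pm$F1), rep(1, 4))
  expect_true(all(pm$confusion[lower.tri(pm$confusion)] == 0))

  # confusion in the style of the study's model-1 matrix: 369 correct CR,
  # 65 CR records predicted as CS; other classes perfect with 600 each
  cm <- matrix(0L, 4, 4, dimnames = list(observed = names(sort(TREATMENT_LABELS)),
                                         predicted = names(sort(TREATMENT_LABELS))))
  diag(cm) <- c(600L, 369L, 600L, 600L)
  cm["CR", "CS"] <- 65L
  met <- class_metrics(cm)
  # direct-formula oracle: Ac_a = Cpred_a / (all predictions labelled a)
  expect_equal(unname(met$Ac["CS"]), 600 / (600 + 65))
  expect_equal(unname(met$Ac["CR"]), 369 / 369)
  prec_cs <- 600 / 665; rec_cs <- 1
  expect_equal(unname(met$F1["CS"]),
               2 * prec_cs * rec_cs / (prec_cs + rec_cs))
  prec_cr <- 1; rec_cr <- 369 / 434
  expect_equal(unname(met$F1["CR"]),
               2 * prec_cr * rec_cr / (prec_cr + rec_cr))

  # constant single-class predictor on balanced labels
  konst <- class_metrics(confusion_matrix(rep(0:3, each = 25),
                                          rep(2L, 100)))
  expect_equal(unname(konst$recall), c(0, 0, 1, 0))
  expect_equal(unname(konst$Ac["BR"]), 1 / 4)
  expect_error(class_metrics(matrix(-1, 4, 4)), "negative")
  expect_error(confusion_matrix(c(0, 5), c(0, 1)), "outside")
})

test_that("cross-validation validates every segment exactly once", {
  b <- tiny_bundle_cached()
  ds <- build_dataset(b, seed = 71)
  spec <- cnn_spec(input_len = 1000L, n_channels = 3L,
                   filters = c(2L, 3L, 4L, 5L), kernel = 3L, dropout = 0,
                   batch_size = 192L)
  cv <- cross_validate(ds, spec, epochs = 1L, seed = 72)
  expect_length(cv$metrics, 3L)
  counted <- Reduce(`+`, lapply(cv$metrics, function(mm) sum(mm$confusion)))
  expect_equal(counted, nrow(ds$meta))
  expect_length(cv$mean_F1, 4L)
  expect_true(all(cv$mean_F1 >= 0 & cv$mean_F1 <= 1))
})
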