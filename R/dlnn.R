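#' Training configuration for the pixel-wise classifier
#'
#' @param batch_size mini-batch size (>= 1).
#' @param epochs number of passes over the training split.
#' @param learning_rate gradient-descent step size (> 0).
#' @param split_fraction fraction of labelled rows used for training; the
#'   remainder validates per-epoch model selection. Default 0.8 (80/20).
#' @param seed integer seed governing the split, weight initialization and
#'   batch shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 256L, epochs = 300L,
                            learning_rate = 0.05, split_fraction = 0.8,
                            seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie strictly inside (0, 1)")
  if (batch_size < 1L) stop("batch_size must be at least 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Randomly split a labelled table into training and validation parts
#'
#' Uniformly random, disjoint, exhaustive partition with
#' `floor(n * fraction)` training rows; deterministic given `seed`.
#'
#' @param table a labelled `feature_table`.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `validation` (feature tables
#'   sharing the parent's scaling).
#' @export
split_train_validation <- function(table, fraction = 0.8, seed = 1L) {
  if (is.null(table$label)) stop("missing-labels error: table is unlabelled")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- nrow(table)
  n_train <- floor(n * fraction)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_train))
  sc <- attr(table, "scaling")
  take <- function(i) {
    t2 <- table[i, , drop = FALSE]
    attr(t2, "scaling") <- sc
    class(t2) <- class(table)
    t2
  }
  list(train = take(sort(idx)), validation = take(setdiff(seq_len(n), idx)))
}

FEATURES <- c("blue", "green", "red", "depth")

feature_matrix <- function(table) {
  if (is.data.frame(table)) as.matrix(table[FEATURES]) else as.matrix(table)
}

standardize <- function(X, scaling) {
  sweep(sweep(X, 2L, scaling$mean), 2L, scaling$sd, `/`)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass on an already-standardized matrix
forward_std <- function(W, B, A) {
  L <- length(W)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% W[[l]], 2L, B[[l]], `+`)
    A <- if (l < L) pmax(Z, 0) else sigmoid(Z)
  }
  p <- as.vector(A)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

new_model <- function(layer_sizes, weights, biases, scaling,
                      threshold = 0.5, seed = NA_integer_) {
  stopifnot(utils::tail(layer_sizes, 1L) == 1L, threshold > 0, threshold < 1)
  structure(list(layer_sizes = as.integer(layer_sizes), weights = weights,
                 biases = biases, threshold = threshold, scaling = scaling,
                 seed = seed),
            class = "po_dlnn")
}

#' @export
print.po_dlnn <- function(x, ...) {
  cat(sprintf("<po_dlnn> layers %s, ReLU hidden / sigmoid output, threshold %.2f, seed %s\n",
              paste(x$layer_sizes, collapse = "-"), x$threshold, x$seed))
  invisible(x)
}

# He-style initialization from the config seed
init_model <- function(layer_sizes, scaling, threshold, seed) {
  L <- length(layer_sizes) - 1L
  withr::with_seed(as.integer(seed), {
    W <- vector("list", L); B <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      W[[l]] <- matrix(stats::rnorm(fan_in * layer_sizes[l + 1L],
                                    0, sqrt(2 / fan_in)),
                       fan_in, layer_sizes[l + 1L])
      B[[l]] <- rep(0, layer_sizes[l + 1L])
    }
    new_model(layer_sizes, W, B, scaling, threshold, as.integer(seed))
  })
}

#' Forward pass: per-pixel probability of P. oceanica
#'
#' Standardizes the features with the scaling stored in the model, then
#' alternates affine maps and ReLU through the hidden layers and applies a
#' sigmoid at the single output unit. A pure function of (model, features).
#'
#' @param model a `po_dlnn` model.
#' @param features a `feature_table` or numeric matrix with columns
#'   blue, green, red, depth.
#' @return numeric vector of probabilities strictly inside (0, 1).
#' @export
forward <- function(model, features) {
  X <- feature_matrix(features)
  if (ncol(X) != model$layer_sizes[1L])
    stop("shape error: feature arity ", ncol(X), " does not match input layer ",
         model$layer_sizes[1L])
  # probabilities are clamped to (0,1) open interval for finite cross-entropy
  forward_std(model$weights, model$biases, standardize(X, model$scaling))
}

bce_loss <- function(p, y) -mean(y * log(p) + (1 - y) * log(1 - p))

#' Train the pixel-wise deep feed-forward classifier
#'
#' Mini-batch gradient descent on binary cross-entropy, with forward and
#' backpropagation through ReLU hidden layers and a sigmoid output. Rows
#' are canonicalized by pixel index before the seeded shuffle, so the
#' result does not depend on input row order. The labelled table is split
#' `split_fraction` / rest into training and validation; the returned model
#' is the per-epoch snapshot with minimum validation loss.
#'
#' @param table labelled `feature_table` containing both classes.
#' @param layer_sizes hidden layer widths, default `c(32, 16)`; the input
#'   (4) and output (1) layers are implied.
#' @param config a [training_config()].
#' @return list with `model` (a `po_dlnn`) and `history` (data.frame of
#'   epoch, training loss, validation loss).
#' @export
train_classifier <- function(table, layer_sizes = c(32L, 16L),
                             config = training_config()) {
  if (is.null(table$label)) stop("missing-labels error: table is unlabelled")
  if (length(unique(table$label)) < 2L)
    stop("degenerate-labels error: training data contains a single class")
  if (is.null(attr(table, "scaling")))
    attr(table, "scaling") <- list(
      mean = vapply(table[FEATURES], mean, 0),
      sd = vapply(table[FEATURES], function(v) {
        s <- stats::sd(v); if (is.na(s) || s == 0) 1 else s
      }, 0))
  # canonical row order: results independent of the caller's row order
  if (!is.null(table$row)) {
    ord <- order(table$row, table$col)
    sc <- attr(table, "scaling")
    table <- table[ord, , drop = FALSE]
    attr(table, "scaling") <- sc
  }
  parts <- split_train_validation(table, config$split_fraction, config$seed)
  Xtr <- standardize(feature_matrix(parts$train), attr(table, "scaling"))
  ytr <- parts$train$label
  Xva <- standardize(feature_matrix(parts$validation), attr(table, "scaling"))
  yva <- parts$validation$label
  sizes <- c(ncol(Xtr), as.integer(layer_sizes), 1L)
  model <- init_model(sizes, attr(table, "scaling"), 0.5, config$seed)
  W <- model$weights; B <- model$biases
  L <- length(W)
  n <- nrow(Xtr)
  lr <- config$learning_rate
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, W = W, B = B)
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1L, n, by = config$batch_size)
      for (s in batch_starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- Xtr[rows, , drop = FALSE]
        yb <- ytr[rows]
        m <- length(rows)
        # forward, caching activations
        A <- vector("list", L + 1L)
        A[[1L]] <- Xb
        for (l in seq_len(L)) {
          Z <- sweep(A[[l]] %*% W[[l]], 2L, B[[l]], `+`)
          A[[l + 1L]] <- if (l < L) pmax(Z, 0) else sigmoid(Z)
        }
        # backprop: sigmoid+BCE gives dZ_out = p - y
        dZ <- A[[L + 1L]] - yb
        for (l in rev(seq_len(L))) {
          dW <- crossprod(A[[l]], dZ) / m
          dB <- colMeans(dZ)
          if (l > 1L) {
            dA <- dZ %*% t(W[[l]])
            dZ <- dA * (A[[l]] > 0)  # ReLU gate
          }
          W[[l]] <- W[[l]] - lr * dW
          B[[l]] <- B[[l]] - lr * dB
        }
      }
      tr_loss <- bce_loss(forward_std(W, B, Xtr), ytr)
      va_loss <- bce_loss(forward_std(W, B, Xva), yva)
      history[epoch, ] <- list(epoch, tr_loss, va_loss)
      if (va_loss < best$loss) best <- list(loss = va_loss, W = W, B = B)
    }
  })
  final <- new_model(sizes, best$W, best$B, attr(table, "scaling"), 0.5,
                     config$seed)
  list(model = final, history = history,
       validation = parts$validation, train = parts$train)
}

#' Threshold probabilities into binary classes
#'
#' Class 1 (PO) when the probability is at least the model threshold; a
#' probability of exactly 0.5 at the default threshold maps to class 1.
#'
#' @param model a `po_dlnn` (its `threshold` is used), or a single numeric
#'   threshold in (0, 1).
#' @param probability numeric vector of probabilities.
#' @return integer vector of 0/1.
#' @export
classify <- function(model, probability) {
  thr <- if (inherits(model, "po_dlnn")) model$threshold else model
  stopifnot(is.numeric(thr), length(thr) == 1L, thr > 0, thr < 1)
  as.integer(probability >= thr)
}

#' Predict a binary map over a raster grid
#'
#' Runs the classifier on every row of the feature table and writes the
#' classes back to the table's pixel indices; pixels absent from the table
#' stay invalid.
#'
#' @param model a `po_dlnn`.
#' @param table `feature_table` built from `target`'s grid.
#' @param target `raster_grid` defining shape and georeference.
#' @return a `label_raster` of predictions.
#' @export
predict_map <- function(model, table, target) {
  d <- grid_dim(target)
  lab <- matrix(NA_real_, d[1L], d[2L])
  if (nrow(table) > 0L) {
    if (any(table$row < 1L | table$row > d[1L] |
            table$col < 1L | table$col > d[2L]))
      stop("integrity error: pixel index outside the target raster")
    cls <- classify(model, forward(model, table))
    lab[cbind(table$row, table$col)] <- cls
  }
  label_raster(lab, target$pixel_size, target$xll, target$yll)
}

MODEL_FORMAT_VERSION <- 1L

#' Persist a trained model as a self-describing JSON file
#'
#' Records layer sizes, weights, biases, feature scaling, threshold and
#' seed at full floating-point precision, with a format version; reloading
#' reproduces forward outputs bit-identically.
#'
#' @param model a `po_dlnn`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(format = "posimap-dlnn", version = MODEL_FORMAT_VERSION,
              layer_sizes = model$layer_sizes,
              weights = lapply(model$weights, function(w)
                list(dim = dim(w), data = as.vector(w))),
              biases = model$biases,
              scaling = model$scaling,
              threshold = model$threshold,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("format error: unreadable model file: ",
                                           conditionMessage(e)))
  if (!identical(obj$format, "posimap-dlnn"))
    stop("format error: not a posimap model file")
  if (!identical(as.integer(obj$version %||% -1L), MODEL_FORMAT_VERSION))
    stop("format error: unsupported model format version")
  need <- c("layer_sizes", "weights", "biases", "scaling", "threshold")
  if (!all(need %in% names(obj)))
    stop("format error: model file missing fields: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  W <- lapply(obj$weights, function(w)
    matrix(as.numeric(unlist(w$data)), w$dim[[1L]], w$dim[[2L]]))
  B <- lapply(obj$biases, function(b) as.numeric(unlist(b)))
  sc <- list(mean = as.numeric(unlist(obj$scaling$mean)),
             sd = as.numeric(unlist(obj$scaling$sd)))
  names(sc$mean) <- names(sc$sd) <- FEATURES[seq_along(sc$mean)]
  sizes <- as.integer(unlist(obj$layer_sizes))
  if (length(W) != length(sizes) - 1L)
    stop("format error: layer count disagrees with weights")
  for (l in seq_along(W)) {
    if (!identical(dim(W[[l]]), c(sizes[l], sizes[l + 1L])) ||
        length(B[[l]]) != sizes[l + 1L])
      stop("format error: weight/bias shapes disagree with layer sizes")
  }
  new_model(sizes, W, B, sc, obj$threshold,
            as.integer(obj$seed %||% NA_integer_))
}
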