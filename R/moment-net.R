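#' @useDynLib sonomoment, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

cnn_filters_default <- c(8L, 16L, 32L, 32L, 32L, 32L, 32L)

pool_out <- function(n, pool) floor((n - pool) / 2) + 1

#' Build the 31-layer CNN regressor specification
#'
#' One image input layer; seven sets of convolution (stride 1, 'same'
#' padding), batch normalization and ReLU, with average pooling (stride 2,
#' no padding) after sets 1--6 only; dropout after set 7's ReLU; one fully
#' connected unit; a regression output layer. Filter counts are 8, 16 and
#' then 32 for the remaining sets.
#'
#' @param input_hw `c(rows, cols)` of the input image.
#' @param kernel_size convolution kernel side (odd; default 3).
#' @param pool_size average-pooling window side (default 2; stride is 2).
#' @param filters per-set filter counts (length 7).
#' @param dropout dropout probability after set 7 (default 0.20).
#' @return An object of class `cnn_spec` with a 31-row `layers` tibble.
#' @export
build_cnn <- function(input_hw, kernel_size = 3L, pool_size = 2L,
                      filters = cnn_filters_default, dropout = 0.20) {
  stopifnot(length(input_hw) == 2, length(filters) == 7)
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd", call. = FALSE)
  h <- input_hw[1]; w <- input_hw[2]
  for (s in 1:6) {
    h2 <- pool_out(h, pool_size); w2 <- pool_out(w, pool_size)
    if (h2 < 1 || w2 < 1) {
      stop(sprintf("input %dx%d collapses at pooling layer of set %d (pool_%d)",
                   input_hw[1], input_hw[2], s, s), call. = FALSE)
    }
    h <- h2; w <- w2
  }
  rows <- list(list(name = "input", type = "input", set = NA_integer_))
  for (s in 1:7) {
    rows <- c(rows, list(
      list(name = sprintf("conv_%d", s), type = "conv", set = s),
      list(name = sprintf("bn_%d", s), type = "batchnorm", set = s),
      list(name = sprintf("relu_%d", s), type = "relu", set = s)))
    if (s <= 6) {
      rows <- c(rows, list(list(name = sprintf("pool_%d", s),
                                type = "avgpool", set = s)))
    }
  }
  rows <- c(rows, list(
    list(name = "dropout", type = "dropout", set = 7L),
    list(name = "fc", type = "fc", set = NA_integer_),
    list(name = "regression", type = "regression", set = NA_integer_)))
  layers <- tibble::tibble(
    layer = seq_along(rows),
    name = vapply(rows, `[[`, character(1), "name"),
    type = vapply(rows, `[[`, character(1), "type"),
    set = vapply(rows, function(r) as.integer(r$set), integer(1))
  )
  structure(list(
    input_hw = as.integer(input_hw), kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size), filters = as.integer(filters),
    dropout = dropout, layers = layers,
    fc_inputs = h * w * filters[7]
  ), class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> %d layers, input %dx%d, fc inputs %d\n",
              nrow(x$layers), x$input_hw[1], x$input_hw[2], x$fc_inputs))
  invisible(x)
}

#' Per-layer output shapes of a CNN spec
#'
#' Propagates `(rows, cols, channels)` through the network: 'same'
#' convolutions preserve the spatial size, pooling maps `n` to
#' `floor((n - pool) / 2) + 1`.
#'
#' @param spec a [build_cnn()] spec.
#' @return Tibble with `layer`, `name`, `type`, `rows`, `cols`, `channels`
#'   (fc and regression layers report their unit count in `channels` with
#'   1x1 spatial size).
#' @export
layer_output_shapes <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  h <- spec$input_hw[1]; w <- spec$input_hw[2]; ch <- 1L
  out <- vector("list", nrow(spec$layers))
  for (i in seq_len(nrow(spec$layers))) {
    ty <- spec$layers$type[i]
    s <- spec$layers$set[i]
    if (ty == "conv") ch <- spec$filters[s]
    if (ty == "avgpool") {
      h <- pool_out(h, spec$pool_size)
      w <- pool_out(w, spec$pool_size)
    }
    if (ty %in% c("fc", "regression")) { h <- 1L; w <- 1L; ch <- 1L }
    out[[i]] <- c(rows = h, cols = w, channels = ch)
  }
  shp <- do.call(rbind, out)
  tibble::tibble(spec$layers, rows = shp[, "rows"], cols = shp[, "cols"],
                 channels = shp[, "channels"])
}

#' Training schedule configuration
#'
#' Defaults follow the reference protocol: mini-batch 128, 30 epochs,
#' learning rate 0.001 dropping to 0.0001 after epoch 20, SGD with momentum
#' 0.9, per-epoch shuffling, validation every `floor(n_train / mini_batch)`
#' iterations.
#'
#' @param mini_batch mini-batch size (>= 1).
#' @param max_epochs maximum epochs (>= 1).
#' @param lr_initial,lr_final learning rates before/after `lr_drop_epoch`.
#' @param lr_drop_epoch epoch after which the final rate applies.
#' @param momentum SGD momentum coefficient.
#' @param bn_momentum running-statistics update rate for batch norm.
#' @param validation_frequency iterations between validation passes;
#'   `NULL` computes `floor(n_train / mini_batch)`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(mini_batch = 128L, max_epochs = 30L,
                         lr_initial = 0.001, lr_final = 0.0001,
                         lr_drop_epoch = 20L, momentum = 0.9,
                         bn_momentum = 0.1, validation_frequency = NULL) {
  if (mini_batch < 1) stop("mini_batch must be >= 1", call. = FALSE)
  if (max_epochs < 1) stop("max_epochs must be >= 1", call. = FALSE)
  if (lr_initial <= 0 || lr_final <= 0) stop("learning rates must be positive",
                                             call. = FALSE)
  structure(list(mini_batch = as.integer(mini_batch),
                 max_epochs = as.integer(max_epochs),
                 lr_initial = lr_initial, lr_final = lr_final,
                 lr_drop_epoch = as.integer(lr_drop_epoch),
                 momentum = momentum, bn_momentum = bn_momentum,
                 validation_frequency = validation_frequency),
            class = "train_config")
}

#' Leave-one-speed-out cross-validation splits
#'
#' Per held-out speed `s`: training = the first `fit_cycles` cycles of every
#' other speed; validation = the first `fit_cycles` cycles of speed `s`;
#' prediction = the remaining cycles of all speeds. With 5 speeds and 8
#' cycles each this yields 5 folds of 20 / 5 / 15 cycles (62.5% of cycles in
#' train+validation).
#'
#' @param dataset a `synthetic_dataset` or a data frame with columns
#'   `speed` and `cycle_id` describing the available stance cycles.
#' @param fit_cycles cycles per speed assigned to fitting (default 5).
#' @return An object of class `data_split`: tibble with `held_out` and
#'   list-columns `train`, `validation`, `prediction` of cycle row indices.
#' @export
make_splits <- function(dataset, fit_cycles = 5L) {
  meta <- if (inherits(dataset, "synthetic_dataset")) {
    tibble::tibble(
      speed = vapply(dataset$cycles, `[[`, numeric(1), "speed"),
      cycle_id = vapply(dataset$cycles, `[[`, integer(1), "cycle_id")
    )
  } else {
    tibble::as_tibble(dataset[, c("speed", "cycle_id")])
  }
  speeds <- sort(unique(meta$speed))
  if (length(speeds) < 2) stop("need at least 2 speeds", call. = FALSE)
  counts <- table(meta$speed)
  if (any(counts < fit_cycles + 1)) {
    stop(sprintf("every speed needs at least %d cycles", fit_cycles + 1),
         call. = FALSE)
  }
  fit_idx <- function(sp) {
    rows <- which(meta$speed == sp)
    rows[order(meta$cycle_id[rows])][seq_len(fit_cycles)]
  }
  pred_idx <- function(sp) {
    rows <- which(meta$speed == sp)
    rows[order(meta$cycle_id[rows])][-seq_len(fit_cycles)]
  }
  folds <- lapply(speeds, function(sp) {
    tibble::tibble(
      held_out = sp,
      train = list(sort(unlist(lapply(setdiff(speeds, sp), fit_idx)))),
      validation = list(fit_idx(sp)),
      prediction = list(sort(unlist(lapply(speeds, pred_idx))))
    )
  })
  out <- do.call(rbind, folds)
  class(out) <- c("data_split", class(out))
  out
}

#' Gather fold images and labels from a synthetic dataset
#'
#' Concatenates the image frames and moment labels of the given cycle
#' indices into a single `H x W x N` stack and label vector.
#'
#' @param dataset a `synthetic_dataset` (image mode).
#' @param idx cycle row indices (e.g. from [make_splits()]).
#' @return List with `images`, `labels`, `speed` (per frame), `cycle`
#'   (per frame).
#' @export
collect_cycles <- function(dataset, idx) {
  cyc <- dataset$cycles[idx]
  ns <- vapply(cyc, function(cc) dim(cc$frames)[3], integer(1))
  hw <- dim(cyc[[1]]$frames)[1:2]
  images <- array(0, dim = c(hw[1], hw[2], sum(ns)))
  labels <- numeric(sum(ns))
  speed <- numeric(sum(ns)); cycle <- integer(sum(ns))
  at <- 0L
  for (i in seq_along(cyc)) {
    rng <- at + seq_len(ns[i])
    images[, , rng] <- cyc[[i]]$frames
    labels[rng] <- cyc[[i]]$moment
    speed[rng] <- cyc[[i]]$speed
    cycle[rng] <- idx[i]
    at <- at + ns[i]
  }
  list(images = images, labels = labels, speed = speed, cycle = cycle)
}

as_datastore <- function(x) {
  if (is.list(x) && !is.null(x$fetch) && !is.null(x$n)) return(x)
  if (is.array(x) && length(dim(x)) == 3) {
    dims <- dim(x)
    return(list(n = dims[3], hw = dims[1:2],
                fetch = function(idx) x[, , idx, drop = FALSE]))
  }
  stop("images must be an H x W x N array or a datastore list(n, hw, fetch)",
       call. = FALSE)
}

init_cnn_params <- function(spec) {
  k <- spec$kernel_size
  chans <- c(1L, spec$filters)
  conv_w <- conv_b <- bn_gamma <- bn_beta <- bn_rmean <- bn_rvar <- vector("list", 7)
  for (s in 1:7) {
    fan_in <- chans[s] * k * k
    lim <- sqrt(6 / fan_in)
    K <- spec$filters[s]
    conv_w[[s]] <- matrix(stats::runif(K * fan_in, -lim, lim), K, fan_in)
    conv_b[[s]] <- numeric(K)
    bn_gamma[[s]] <- rep(1, K)
    bn_beta[[s]] <- numeric(K)
    bn_rmean[[s]] <- numeric(K)
    bn_rvar[[s]] <- rep(1, K)
  }
  lim <- sqrt(6 / spec$fc_inputs)
  list(conv_w = conv_w, conv_b = conv_b, bn_gamma = bn_gamma,
       bn_beta = bn_beta, bn_rmean = bn_rmean, bn_rvar = bn_rvar,
       fc_w = stats::runif(spec$fc_inputs, -lim, lim), fc_b = 0)
}

zero_like_grads <- function(params) {
  list(conv_w = lapply(params$conv_w, function(w) w * 0),
       conv_b = lapply(params$conv_b, function(b) b * 0),
       bn_gamma = lapply(params$bn_gamma, function(g) g * 0),
       bn_beta = lapply(params$bn_beta, function(b) b * 0),
       fc_w = params$fc_w * 0, fc_b = 0)
}

sgd_momentum_step <- function(params, vel, grads, lr, mom) {
  for (s in 1:7) {
    for (f in c("conv_w", "conv_b", "bn_gamma", "bn_beta")) {
      vel[[f]][[s]] <- mom * vel[[f]][[s]] - lr * grads[[f]][[s]]
      params[[f]][[s]] <- params[[f]][[s]] + vel[[f]][[s]]
    }
  }
  vel$fc_w <- mom * vel$fc_w - lr * grads$fc_w
  params$fc_w <- params$fc_w + vel$fc_w
  vel$fc_b <- mom * vel$fc_b - lr * grads$fc_b
  params$fc_b <- params$fc_b + vel$fc_b
  list(params = params, vel = vel)
}

#' Train the moment-regression CNN on an image stream
#'
#' Stochastic gradient descent with momentum on the mean-squared-error
#' regression loss. Images are consumed in mini-batch chunks through a
#' datastore (the full set is never required in one tensor), shuffled each
#' epoch; inputs are zero-centered by the training-set mean image; batch
#' normalization keeps running statistics for inference. Deterministic for a
#' fixed seed.
#'
#' @param spec a [build_cnn()] spec.
#' @param images `H x W x N` array matching `spec$input_hw`, or a datastore
#'   `list(n, hw, fetch(idx))`.
#' @param labels numeric moment labels in Nm, length N.
#' @param config a [train_config()].
#' @param validation optional `list(images, labels)` for scheduled
#'   validation passes.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return An object of class `moment_cnn`: spec, fitted parameters,
#'   training-set mean image, seed, config and a per-iteration `record`
#'   tibble (`iteration`, `epoch`, `loss`, `rmse`, `val_rmse`).
#' @export
train_moment_net <- function(spec, images, labels, config = train_config(),
                             validation = NULL, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(config, "train_config"))
  ds <- as_datastore(images)
  n <- ds$n
  if (length(labels) != n) stop("labels must match the image count", call. = FALSE)
  if (!all(is.finite(labels))) stop("labels must be finite", call. = FALSE)
  probe <- ds$fetch(1L)
  if (!all(dim(probe)[1:2] == spec$input_hw)) {
    stop(sprintf("image size %dx%d does not match spec input %dx%d",
                 dim(probe)[1], dim(probe)[2], spec$input_hw[1],
                 spec$input_hw[2]), call. = FALSE)
  }

  # training-set mean image, streamed in chunks
  mean_img <- matrix(0, spec$input_hw[1], spec$input_hw[2])
  for (start in seq(1L, n, by = 512L)) {
    idx <- start:min(start + 511L, n)
    chunk <- ds$fetch(idx)
    mean_img <- mean_img + rowSums(chunk, dims = 2)
  }
  mean_img <- mean_img / n

  params <- with_seed(substream_seed(seed, "init"), init_cnn_params(spec))
  vel <- zero_like_grads(params)
  nb <- config$mini_batch
  val_freq <- config$validation_frequency
  if (is.null(val_freq)) val_freq <- max(1L, floor(n / nb))

  rec <- list()
  iter <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    lr <- if (epoch > config$lr_drop_epoch) config$lr_final else config$lr_initial
    set.seed(substream_seed(seed, paste0("epoch/", epoch)))
    ord <- sample.int(n)
    for (start in seq(1L, n, by = nb)) {
      idx <- ord[start:min(start + nb - 1L, n)]
      X <- ds$fetch(idx)
      X <- X - c(mean_img)
      mask <- matrix((stats::runif(spec$fc_inputs * length(idx)) >= spec$dropout) * 1,
                     spec$fc_inputs, length(idx))
      res <- cnn_pass(X, labels[idx], params, spec$kernel_size,
                      spec$pool_size, TRUE, TRUE, mask, spec$dropout)
      iter <- iter + 1L
      if (!is.finite(res$loss)) {
        stop(sprintf("training diverged (non-finite loss) at iteration %d", iter),
             call. = FALSE)
      }
      upd <- sgd_momentum_step(params, vel, res$grads, lr, config$momentum)
      params <- upd$params; vel <- upd$vel
      bm <- config$bn_momentum
      for (s in 1:7) {
        params$bn_rmean[[s]] <- (1 - bm) * params$bn_rmean[[s]] + bm * res$bn_mu[[s]]
        params$bn_rvar[[s]] <- (1 - bm) * params$bn_rvar[[s]] + bm * res$bn_var[[s]]
      }
      val_rmse <- NA_real_
      if (!is.null(validation) && iter %% val_freq == 0) {
        vp <- cnn_infer(params, validation$images, spec)
        val_rmse <- sqrt(mean((vp - validation$labels)^2))
      }
      rec[[iter]] <- c(iteration = iter, epoch = epoch, loss = res$loss,
                       rmse = sqrt(res$loss), val_rmse = val_rmse)
    }
    if (verbose) {
      ep_loss <- mean(vapply(rec[(iter - floor(n / nb)):iter],
                             function(r) r[["loss"]], numeric(1)), na.rm = TRUE)
      message(sprintf("epoch %d: mean loss %.4g", epoch, ep_loss))
    }
  }
  record <- tibble::as_tibble(do.call(rbind, rec))
  structure(list(spec = spec, params = params, mean_image = mean_img,
                 config = config, seed = seed, record = record),
            class = "moment_cnn")
}

# chunked inference on centered images using running BN statistics
cnn_infer <- function(params, images, spec, mean_img = NULL, chunk = 256L) {
  ds <- as_datastore(images)
  preds <- numeric(ds$n)
  for (start in seq(1L, ds$n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ds$n)
    X <- ds$fetch(idx)
    if (!is.null(mean_img)) X <- X - c(mean_img)
    res <- cnn_pass(X, numeric(0), params, spec$kernel_size, spec$pool_size,
                    FALSE, FALSE, matrix(0, 1, 1), 0)
    preds[idx] <- res$preds
  }
  preds
}

#' Predict moments for an image sequence
#'
#' One scalar moment per frame, in label units (Nm); dropout is inactive
#' and batch normalization uses the running statistics frozen at training.
#'
#' @param object a trained [train_moment_net()] model.
#' @param images `H x W x N` array or datastore matching the model input.
#' @param chunk frames per inference chunk.
#' @param ... unused.
#' @return Numeric vector of length N.
#' @export
predict.moment_cnn <- function(object, images, chunk = 256L, ...) {
  ds <- as_datastore(images)
  probe <- ds$fetch(1L)
  if (!all(dim(probe)[1:2] == object$spec$input_hw)) {
    stop("image size does not match the trained model input", call. = FALSE)
  }
  cnn_infer(object$params, ds, object$spec, object$mean_image, chunk)
}

#' @export
print.moment_cnn <- function(x, ...) {
  fin <- utils::tail(x$record, 1)
  cat(sprintf("<moment_cnn> input %dx%d, %d iterations, final train RMSE %.4g Nm\n",
              x$spec$input_hw[1], x$spec$input_hw[2], nrow(x$record), fin$rmse))
  invisible(x)
}
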