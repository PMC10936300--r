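# independent shape-propagation oracle: plain loop over the set structure
shape_oracle <- function(hw, filters = c(8, 16, 32, 32, 32, 32, 32),
                         pool = 2) {
  h <- hw[1]; w <- hw[2]
  for (s in 1:6) {
    h <- floor((h - pool) / 2) + 1
    w <- floor((w - pool) / 2) + 1
  }
  c(rows = h, cols = w, fc_inputs = h * w * filters[7])
}

test_that("the built network has the 31-layer architecture", {
  spec <- build_cnn(c(300, 300))
  expect_equal(nrow(spec$layers), 31)
  expect_equal(sum(spec$layers$type == "avgpool"), 6)
  expect_equal(sum(spec$layers$type == "conv"), 7)
  expect_equal(sum(spec$layers$type == "batchnorm"), 7)
  expect_equal(sum(spec$layers$type == "relu"), 7)
  expect_equal(sum(spec$layers$type == "dropout"), 1)
  # set 7 has no pooling
  expect_false("pool_7" %in% spec$layers$name)
  # architecture is input-size independent
  spec2 <- build_cnn(c(100, 100))
  expect_identical(spec$layers, spec2$layers)
  expect_equal(spec$filters, c(8, 16, 32, 32, 32, 32, 32))
  # too-small inputs collapse before set 6
  expect_error(build_cnn(c(16, 16)), "pool_")
})

test_that("shape propagation matches the standalone oracle for all ROIs", {
  for (hw in list(c(100, 100), c(200, 200), c(300, 300))) {
    spec <- build_cnn(hw)
    ora <- shape_oracle(hw)
    expect_equal(spec$fc_inputs, unname(ora["fc_inputs"]))
    sh <- layer_output_shapes(spec)
    last_pool <- max(which(sh$type == "avgpool"))
    expect_equal(sh$rows[last_pool], unname(ora["rows"]))
    expect_equal(sh$cols[last_pool], unname(ora["cols"]))
    # 'same' convolutions preserve spatial size
    for (i in which(sh$type == "conv")) {
      expect_equal(sh$rows[i], sh$rows[i - 1])
    }
  }
  expect_equal(build_cnn(c(100, 100))$fc_inputs, 32)
  expect_equal(build_cnn(c(200, 200))$fc_inputs, 288)
  expect_equal(build_cnn(c(300, 300))$fc_inputs, 512)
})

test_that("leave-one-speed-out splits honor the 20/5/15 cycle design", {
  meta <- expand.grid(cycle_id = 1:8,
                      speed = c(0.50, 0.75, 1.00, 1.25, 1.50))
  sp <- make_splits(meta)
  expect_equal(nrow(sp), 5)
  for (i in seq_len(nrow(sp))) {
    tr <- sp$train[[i]]; va <- sp$validation[[i]]; pr <- sp$prediction[[i]]
    expect_length(tr, 20)
    expect_length(va, 5)
    expect_length(pr, 15)
    expect_length(intersect(tr, va), 0)
    expect_length(intersect(union(tr, va), pr), 0)
    # validation cycles all come from the held-out speed
    expect_true(all(meta$speed[va] == sp$held_out[i]))
    expect_true(all(meta$speed[tr] != sp$held_out[i]))
  }
  expect_equal(length(union(sp$train[[1]], sp$validation[[1]])) / nrow(meta),
               0.625)
  expect_error(make_splits(meta[meta$cycle_id <= 4, ]), "at least")
})

# small learnable image set: brightness pattern scales with the label
make_toy_images <- function(n, hw = 64, seed = 1) {
  with_seed(seed, {
    labels <- runif(n, 0, 100)
    pattern <- outer(seq_len(hw), seq_len(hw),
                     function(i, j) sin(i / 5) * cos(j / 7))
    imgs <- array(0, dim = c(hw, hw, n))
    for (t in seq_len(n)) {
      imgs[, , t] <- 0.5 + 0.4 * (labels[t] / 100) * pattern +
        matrix(rnorm(hw * hw, 0, 0.02), hw, hw)
    }
    list(images = imgs, labels = labels)
  })
}

test_that("training descends and is seed-reproducible", {
  toy <- make_toy_images(96)
  spec <- build_cnn(c(64, 64))
  cfg <- train_config(mini_batch = 32, max_epochs = 3, lr_initial = 0.003,
                      lr_final = 3e-4, lr_drop_epoch = 2)
  m1 <- train_moment_net(spec, toy$images, toy$labels, cfg, seed = 9)
  rec <- m1$record
  first_epoch <- mean(rec$loss[rec$epoch == 1])
  last_epoch <- mean(rec$loss[rec$epoch == max(rec$epoch)])
  expect_lt(last_epoch, first_epoch)
  # identical seed -> identical final weights
  m2 <- train_moment_net(spec, toy$images, toy$labels, cfg, seed = 9)
  expect_identical(m1$params$fc_w, m2$params$fc_w)
  expect_identical(m1$params$conv_w[[4]], m2$params$conv_w[[4]])
  expect_identical(m1$record$loss, m2$record$loss)
  # shape mismatch and bad labels are rejected
  expect_error(train_moment_net(build_cnn(c(100, 100)), toy$images,
                                toy$labels, cfg), "does not match")
  expect_error(train_moment_net(spec, toy$images,
                                c(NA, toy$labels[-1]), cfg), "finite")
})

test_that("a constant target is learned to within 5%", {
  toy <- make_toy_images(64, seed = 3)
  const <- rep(40, 64)
  spec <- build_cnn(c(64, 64))
  cfg <- train_config(mini_batch = 32, max_epochs = 25, lr_initial = 0.005,
                      lr_final = 0.001, lr_drop_epoch = 20)
  m <- train_moment_net(spec, toy$images, const, cfg, seed = 5)
  preds <- predict(m, toy$images)
  expect_lt(sqrt(mean((preds - 40)^2)), 0.05 * 40)
})

test_that("prediction is per-frame, deterministic and unit-preserving", {
  toy <- make_toy_images(48, seed = 4)
  spec <- build_cnn(c(64, 64))
  cfg <- train_config(mini_batch = 24, max_epochs = 2, lr_initial = 0.002,
                      lr_final = 2e-4, lr_drop_epoch = 1)
  m <- train_moment_net(spec, toy$images, toy$labels, cfg, seed = 2)
  preds <- predict(m, toy$images)
  expect_length(preds, 48)
  # repeated identical frame -> identical predictions
  rep_imgs <- toy$images[, , c(5, 5, 5)]
  pr <- predict(m, rep_imgs)
  expect_identical(pr[1], pr[2])
  expect_identical(pr[1], pr[3])
  expect_error(predict(m, array(0, c(32, 32, 2))), "match")
})

test_that("the datastore interface streams without materializing", {
  toy <- make_toy_images(60, seed = 6)
  fetch_count <- 0L
  max_chunk <- 0L
  store <- list(n = 60L, hw = c(64L, 64L), fetch = function(idx) {
    fetch_count <<- fetch_count + 1L
    max_chunk <<- max(max_chunk, length(idx))
    toy$images[, , idx, drop = FALSE]
  })
  spec <- build_cnn(c(64, 64))
  cfg <- train_config(mini_batch = 16, max_epochs = 1, lr_initial = 0.002)
  m <- train_moment_net(spec, store, toy$labels, cfg, seed = 1)
  expect_s3_class(m, "moment_cnn")
  expect_gt(fetch_count, 2L)       # consumed in chunks
  expect_lte(max_chunk, 512L)      # never the whole set at once for batches
})
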