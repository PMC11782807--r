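test_that("MSE loss matches hand values and scales quadratically", {
  expect_equal(mse_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse_loss(c(1, 2), c(3, 2)), 2)  # ((1-3)^2 + 0)/2
  r <- c(0.5, -1, 2)
  expect_equal(mse_loss(3 * r, rep(0, 3)), 9 * mse_loss(r, rep(0, 3)))
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
  expect_error(mse_loss(1:3, 1:2), "length")
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- tiny_config(feature_dim = 4L)
  m <- cinefuse_model(cfg, seed = 7)
  withr::with_seed(1, {
    X <- array(rnorm(2 * 6 * 16), c(2, 6, 16))
    ys <- rnorm(2)
  })
  bg <- cinefuse:::batch_grad(cfg, m$params, X, ys, aux_w = 0.2)
  flat <- cinefuse:::flatten_params(m$params)
  gflat <- cinefuse:::flatten_params(bg$grads)
  lossfn <- function(fl) {
    cinefuse:::batch_grad(cfg, cinefuse:::unflatten_params(fl, m$params),
                          X, ys, aux_w = 0.2)$loss
  }
  eps <- 1e-6
  for (nm in names(flat)) {
    idx <- seq_len(min(4, length(flat[[nm]])))
    for (k in idx) {
      fp <- flat; fp[[nm]][k] <- fp[[nm]][k] + eps
      fm <- flat; fm[[nm]][k] <- fm[[nm]][k] - eps
      g_num <- (lossfn(fp) - lossfn(fm)) / (2 * eps)
      expect_equal(gflat[[nm]][k], g_num, tolerance = 1e-5)
    }
  }
})

test_that("training is reproducible: same seed, identical weights and history", {
  feats <- train_fixture()
  cfg_t <- small_train_config(max_epochs = 8L, patience = 8L, seed = 5)
  m1 <- train_model(feats, cinefuse_model(cinefuse_config(), seed = 2), cfg_t)
  m2 <- train_model(feats, cinefuse_model(cinefuse_config(), seed = 2), cfg_t)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_true(m1$trained)
  m3 <- train_model(feats, cinefuse_model(cinefuse_config(), seed = 3), cfg_t)
  expect_false(identical(m1$params$W1, m3$params$W1))
})

test_that("training beats the predict-the-mean baseline on clean phantoms", {
  feats <- train_fixture()
  m <- train_model(feats, cinefuse_model(cinefuse_config(), seed = 4),
                   small_train_config(max_epochs = 60L, patience = 15L, seed = 4))
  iva <- feats$exams$split == "val"
  baseline <- mean((feats$exams$mPAP[iva] -
                      mean(feats$exams$mPAP[feats$exams$split == "train"]))^2)
  best <- m$history$val_loss[m$best_epoch]
  expect_lt(best, baseline)
  # trained model generalises: positive R^2 on held-out exams
  pr <- predict(m, feats, split = "test")
  expect_gt(r_squared(pr$truth, pr$prediction), 0)
})

test_that("early stopping halts after `patience` epochs without improvement", {
  feats <- train_fixture()
  # a vanishing learning rate cannot improve validation loss after epoch 1
  cfg_t <- train_config(learning_rate = 1e-300, batch_size = 36L,
                        max_epochs = 50L, patience = 3L, seed = 1)
  m <- train_model(feats, cinefuse_model(cinefuse_config(), seed = 1), cfg_t)
  expect_lte(nrow(m$history), 4 + 1)
  expect_equal(m$best_epoch, 1)
})

test_that("checkpointing restores the best validation epoch", {
  feats <- train_fixture()
  m <- train_model(feats, cinefuse_model(cinefuse_config(), seed = 6),
                   small_train_config(max_epochs = 12L, patience = 12L, seed = 6))
  expect_equal(m$history$val_loss[m$best_epoch], min(m$history$val_loss))
  # the returned parameters reproduce the recorded best validation loss
  pv <- predict(m, feats, split = "val")
  expect_equal(mse_loss(pv$prediction, pv$truth),
               m$history$val_loss[m$best_epoch], tolerance = 1e-8)
})

test_that("encoding with augmentation perturbs only the training split, reproducibly", {
  ds <- generate_dataset(phantom_config(), n_train = 2, n_val = 0, n_test = 2,
                         seed = 55)
  cfg <- cinefuse_config()
  plain <- encode_dataset(ds, cfg)
  aug <- augmentation_params(flip_prob = 1)
  a1 <- encode_dataset(ds, cfg, augment = aug, seed = 3)
  a2 <- encode_dataset(ds, cfg, augment = aug, seed = 3)
  expect_identical(a1$X, a2$X)
  itr <- which(ds$exams$split == "train")
  ite <- which(ds$exams$split == "test")
  expect_false(identical(a1$X[itr, , ], plain$X[itr, , ]))
  expect_identical(a1$X[ite, , ], plain$X[ite, , ])
  a3 <- encode_dataset(ds, cfg, augment = aug, seed = 4)
  expect_false(identical(a1$X[itr, , ], a3$X[itr, , ]))
})

test_that("split hygiene is enforced", {
  feats <- train_fixture()
  feats$exams$split[feats$exams$split == "train"] <- "nope"
  expect_error(train_model(feats, cinefuse_model(cinefuse_config())), "empty")
  feats2 <- train_fixture()
  feats2$exams$id[feats2$exams$split == "val"][1] <- feats2$exams$id[1]
  expect_error(train_model(feats2, cinefuse_model(cinefuse_config())), "share")
})
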