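make_patients <- function(n = 2, seed = 1, n_selected = 16, sampler = NULL) {
  sampler <- sampler %||% tiny_sampler(seed = seed, n_selected = n_selected)
  co <- generate_cohort(n, tiny_spec(), seed = seed)
  lapply(co, function(p) {
    vol <- normalize_volume(p$volume)
    box <- box_from_mask(p$mask)
    list(volume = vol, box = box,
         centers = sample_centers(dim(vol$intensities)[1:3], box, sampler,
                                  volume = vol))
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("training runs both objectives and logs the schedule", {
  patients <- make_patients(2, seed = 3)
  net <- build_network(tiny_net(), seed = 1)
  smp <- tiny_sampler(seed = 3, n_selected = 16)
  fit_pu <- train(patients, net, train_config(batch_size = 4, epochs = 2,
                                              mode = "pu", seed = 9),
                  sampler = smp)
  h <- fit_pu$history
  expect_equal(nrow(h), 2 * (2 * 16) %/% 4)
  expect_true(all(is.finite(h$objective)))
  expect_true(all(h$objective >= 0))          # beta = 0: clamped objective
  expect_true(all(h$step_scale %in% c(0.5, 0.5 * 1)))
  fit_nv <- train(patients, net, train_config(batch_size = 4, epochs = 1,
                                              mode = "naive", seed = 9),
                  sampler = smp)
  expect_true(all(is.na(fit_nv$history$branch)))
  expect_false(identical(puboxseg:::flatten_params(fit_pu$network$params),
                         puboxseg:::flatten_params(fit_nv$network$params)))
})

test_that("the discounted branch fires with gamma-scaled steps once overfit", {
  patients <- make_patients(1, seed = 5, n_selected = 24)
  net <- build_network(tiny_net(), seed = 2)
  cfg <- train_config(batch_size = 4, epochs = 6, mode = "pu", seed = 4,
                      pu = pu_loss_config(gamma = 0.25, eta = 0.5))
  fit <- train(patients, net, cfg, sampler = tiny_sampler(seed = 5, n_selected = 24))
  h <- fit$history
  expect_gt(sum(h$branch), 0)                 # the clamp eventually activates
  expect_true(all(h$step_scale[h$branch] == 0.25 * 0.5))
  expect_true(all(h$step_scale[!h$branch] == 0.5))
  # the branch flag is exactly the recorded correction sign
  corr <- h$r_u_minus - 0.75 * h$r_p_minus
  expect_equal(h$branch, corr < 0)
})

test_that("one clamp-inactive step equals a plain ADAM step on the objective", {
  smp <- tiny_sampler(seed = 6, n_selected = 8)
  patients <- make_patients(1, seed = 6, n_selected = 8, sampler = smp)
  netc <- tiny_net(precision = "double")
  net <- build_network(netc, seed = 11)
  cfg <- train_config(batch_size = 8, epochs = 1, mode = "pu", seed = 2)
  fit <- train(patients, net, cfg, sampler = smp)
  expect_equal(nrow(fit$history), 1)
  expect_false(fit$history$branch[1])
  # manual step: same patch multiset, gradient of the unbiased objective
  pb <- puboxseg:::make_patch_batch(patients[[1]]$volume, patients[[1]]$box,
                                    patients[[1]]$centers, smp)
  logits <- unet_forward(net, pb$features)
  dl <- puboxseg:::risk_grad_logits(logits, pb$labels, cfg$pu, "pu")
  g <- puboxseg:::unet_grad(net, pb$features, dl)$grads
  theta0 <- puboxseg:::flatten_params(net$params)
  upd <- puboxseg:::adam_step(theta0, puboxseg:::flatten_params(g),
                              puboxseg:::adam_init(length(theta0)),
                              cfg$learning_rate, cfg$pu$eta)
  got <- puboxseg:::flatten_params(fit$network$params)
  expect_lt(max(abs(got - upd$theta)), 1e-9)
})

test_that("training aborts cleanly on a non-finite objective", {
  patients <- make_patients(1, seed = 8, n_selected = 8)
  net <- build_network(tiny_net(), seed = 1)
  net$params$f_b <- Inf                      # blows up the first forward pass
  expect_error(train(patients, net,
                     train_config(batch_size = 4, epochs = 1, mode = "naive"),
                     sampler = tiny_sampler(seed = 8, n_selected = 8)),
               "non-finite")
})

test_that("training loss decreases on the naive objective", {
  patients <- make_patients(2, seed = 12, n_selected = 24)
  net <- build_network(tiny_net(), seed = 3)
  fit <- train(patients, net,
               train_config(batch_size = 4, epochs = 4, mode = "naive", seed = 1),
               sampler = tiny_sampler(seed = 12, n_selected = 24))
  per_epoch <- tapply(fit$history$objective, fit$history$epoch, mean)
  expect_lt(per_epoch[length(per_epoch)], per_epoch[1])
})

test_that("sliding-window prediction averages overlapping tiles", {
  cfgn <- tiny_net()
  net <- build_network(cfgn, seed = 2)
  net$params$f_W[] <- 0
  net$params$f_b <- 1.2                      # constant logit everywhere
  vol <- multimodal_volume(array(rnorm(16^3 * 4), c(16, 16, 16, 4)))
  smp <- sampler_config(patch_size = 8, seed = 1)
  prob <- predict_volume(net, normalize_volume(vol), sampler = smp)
  expect_equal(dim(prob), c(16, 16, 16))
  expect_true(all(abs(prob - 1 / (1 + exp(-1.2))) < 1e-6))
  expect_true(all(prob >= 0 & prob <= 1))
  expect_error(predict_volume(net, multimodal_volume(array(1, c(4, 4, 4, 4))),
                              sampler = smp), "smaller")
})

test_that("overlap averaging equals a brute-force tile accounting oracle", {
  cfgn <- network_config(in_channels = 2, base_filters = 2, depth = 1,
                         patch_size = 4)
  net <- build_network(cfgn, seed = 7)
  arr <- array(rnorm(8^3), c(8, 8, 8, 1))
  arr[arr == 0] <- 0.1
  vol <- multimodal_volume(arr)
  smp <- sampler_config(patch_size = 4, seed = 1)
  prob <- predict_volume(net, vol, sampler = smp)
  # oracle: enumerate tiles at stride 2, forward each, average by coverage
  acc <- array(0, c(8, 8, 8)); cnt <- array(0, c(8, 8, 8))
  starts <- unique(c(seq(0, 4, by = 2), 4))
  for (sx in starts) for (sy in starts) for (sz in starts) {
    f <- build_multiscale_input(vol, c(sx, sy, sz) + 2L, smp)
    p <- 1 / (1 + exp(-unet_forward(net, f)[, , , 1, 1]))
    xs <- (sx + 1):(sx + 4); ys <- (sy + 1):(sy + 4); zs <- (sz + 1):(sz + 4)
    acc[xs, ys, zs] <- acc[xs, ys, zs] + p
    cnt[xs, ys, zs] <- cnt[xs, ys, zs] + 1
  }
  # single-precision GEMMs round differently for different batch shapes,
  # so the comparison is at float accuracy
  expect_equal(prob, acc / cnt, tolerance = 1e-6)
})

test_that("the model interface is reproducible and self-consistent", {
  co <- generate_cohort(3, tiny_spec(), seed = 20)
  smp <- tiny_sampler(seed = 1, n_selected = 16)
  ctl <- train_config(batch_size = 4, epochs = 1)
  fit1 <- puboxseg(co[1:2], mode = "pu", sampler = smp, net = tiny_net(),
                   control = ctl, seed = 31)
  fit2 <- puboxseg(co[1:2], mode = "pu", sampler = smp, net = tiny_net(),
                   control = ctl, seed = 31)
  expect_identical(coef(fit1), coef(fit2))
  expect_s3_class(fit1, "puboxseg")
  expect_output(print(fit1), "puboxseg model")
  expect_output(print(summary(fit1)), "mean objective")
  prob <- predict(fit1, co[[3]]$volume, type = "prob")
  expect_identical(prob, predict(fit2, co[[3]]$volume, type = "prob"))
  m <- predict(fit1, co[[3]]$volume, type = "mask", threshold = 0.5)
  expect_identical(m, fill_holes(prob >= 0.5))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit1))
})
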