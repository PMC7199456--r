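test_that("voxel cross-entropy matches closed-form values and saturates safely", {
  expect_equal(voxel_ce(0, 0), log(2), tolerance = 1e-12)
  expect_equal(voxel_ce(0, 1), log(2), tolerance = 1e-12)
  expect_lt(voxel_ce(30, 1), 1e-12)
  expect_lt(voxel_ce(-30, 0), 1e-12)
  expect_equal(voxel_ce(1, 0), log(1 + exp(1)), tolerance = 1e-12)  # 1.313262
  # extreme logits neither overflow nor go negative
  expect_true(is.finite(voxel_ce(5000, 0)))
  expect_equal(voxel_ce(5000, 0), 5000)
  expect_true(all(voxel_ce(rnorm(100, sd = 50), rbinom(100, 1, 0.5)) >= 0))
  # vector logits with scalar target recycle over every voxel
  expect_length(voxel_ce(rnorm(7), 0), 7)
  expect_equal(voxel_ce(c(-2, 2), c(0, 1)), c(voxel_ce(-2, 0), voxel_ce(2, 1)))
})

test_that("risk components split the batch by label with own-group means", {
  rc <- risk_components(rep(0, 10), rep(c(0, 1), 5))
  expect_equal(rc$r_p_plus, log(2), tolerance = 1e-12)
  expect_equal(rc$r_u_minus, log(2), tolerance = 1e-12)
  expect_equal(rc$r_p_minus, log(2), tolerance = 1e-12)
  expect_equal(rc$n_pos + rc$n_unl, 10)
  # confident wrong-side positive, confident unlabeled
  rc2 <- risk_components(c(30, 30), c(0, 1))
  expect_equal(rc2$r_p_plus, 30, tolerance = 1e-6)
  expect_lt(rc2$r_u_minus, 1e-6)
  expect_lt(rc2$r_p_minus, 1e-6)   # -log(sigma(30)) is tiny by definition
  expect_error(risk_components(c(1, 2), c(1, 1)), "single label class")
})

test_that("risk functions agree with a per-voxel loop oracle", {
  set.seed(10)
  logits <- rnorm(1000, sd = 4)
  labels <- rbinom(1000, 1, 0.4)
  or <- risk_oracle(logits, labels, pi_p = 0.75)
  rc <- risk_components(logits, labels)
  cfg <- pu_loss_config()
  expect_equal(rc$r_p_plus, or$r_p_plus, tolerance = 1e-9)
  expect_equal(rc$r_u_minus, or$r_u_minus, tolerance = 1e-9)
  expect_equal(rc$r_p_minus, or$r_p_minus, tolerance = 1e-9)
  expect_equal(pu_risk(rc, cfg), or$pu, tolerance = 1e-9)
  expect_equal(nn_pu_risk(rc, cfg)$risk, or$nn_pu, tolerance = 1e-9)
  expect_equal(naive_risk(logits, labels), naive_oracle(logits, labels),
               tolerance = 1e-9)
})

test_that("shared-n averaging rescales each term by its group fraction", {
  set.seed(11)
  logits <- rnorm(200); labels <- rbinom(200, 1, 0.3)
  g <- risk_components(logits, labels, averaging = "group")
  s <- risk_components(logits, labels, averaging = "shared")
  expect_equal(s$r_p_plus, g$r_p_plus * g$n_pos / 200, tolerance = 1e-12)
  expect_equal(s$r_u_minus, g$r_u_minus * g$n_unl / 200, tolerance = 1e-12)
  expect_equal(s$r_p_minus, g$r_p_minus * g$n_pos / 200, tolerance = 1e-12)
})

test_that("PU risks assemble components with the class prior", {
  cfg <- pu_loss_config(pi_p = 0.75)
  comps <- structure(list(r_p_plus = 1.0, r_u_minus = 0.2, r_p_minus = 0.8),
                     class = "risk_components")
  expect_equal(pu_risk(comps, cfg), 0.35, tolerance = 1e-12)
  # clamp inactive whenever the correction term is non-negative
  comps_ok <- structure(list(r_p_plus = 1.0, r_u_minus = 0.7, r_p_minus = 0.8),
                        class = "risk_components")
  nn <- nn_pu_risk(comps_ok, cfg)
  expect_equal(nn$risk, pu_risk(comps_ok, cfg))
  expect_false(nn$correction_negative)
  comps2 <- structure(list(r_p_plus = 1.0, r_u_minus = 0.1, r_p_minus = 0.8),
                      class = "risk_components")
  expect_lt(pu_risk(comps2, cfg), nn_pu_risk(comps2, cfg)$risk)
  expect_equal(nn_pu_risk(comps2, cfg)$risk, 0.75)
  expect_true(nn_pu_risk(comps2, cfg)$correction_negative)
  # crafted batch with a genuinely negative unbiased risk
  logits <- c(rep(-10, 50), rep(10, 50))
  labels <- c(rep(0, 50), rep(1, 50))
  rc <- risk_components(logits, labels)
  expect_lt(pu_risk(rc, cfg), 0)
  expect_gte(nn_pu_risk(rc, cfg)$risk, 0)
})

test_that("losses are invariant to voxel ordering", {
  set.seed(12)
  logits <- rnorm(500); labels <- rbinom(500, 1, 0.5)
  perm <- sample(500)
  a <- risk_components(logits, labels)
  b <- risk_components(logits[perm], labels[perm])
  expect_equal(unclass(a)[1:3], unclass(b)[1:3], tolerance = 1e-12)
  expect_equal(naive_risk(logits, labels), naive_risk(logits[perm], labels[perm]),
               tolerance = 1e-12)
})

test_that("loss config enforces the documented parameter ranges", {
  expect_error(pu_loss_config(pi_p = 1), "strictly inside")
  expect_error(pu_loss_config(beta = 0.8, pi_p = 0.75), "beta")
  expect_error(pu_loss_config(gamma = 0), "gamma")
  cfg <- pu_loss_config()
  expect_equal(cfg$pi_p, 0.75)
  expect_equal(cfg$gamma, 1)
  expect_equal(cfg$eta, 0.5)
  expect_equal(cfg$beta, 0)
})

test_that("the unbiased PU estimator is unbiased on a known population", {
  # fixed linear classifier on a finite labeled population with known prior
  set.seed(77)
  pi_p <- 0.75
  n_pop <- 20000
  is_pos <- rbinom(n_pop, 1, pi_p) == 1
  xfeat <- ifelse(is_pos, rnorm(n_pop, -1), rnorm(n_pop, 1.2))
  logit <- 1.7 * xfeat + 0.3                       # fixed classifier
  labels_true <- as.numeric(!is_pos)               # 1 = negative class
  supervised <- pi_p * mean(voxel_ce(logit[is_pos], 0)) +
    (1 - pi_p) * mean(voxel_ce(logit[!is_pos], 1))
  cfg <- pu_loss_config(pi_p = pi_p)
  n_b <- 500; n_pos_b <- 120; n_unl_b <- 160
  vals <- vapply(seq_len(n_b), function(b) {
    ip <- sample(which(is_pos), n_pos_b)
    iu <- sample.int(n_pop, n_unl_b)               # unlabeled ~ marginal
    lg <- c(logit[ip], logit[iu])
    lb <- c(rep(0, n_pos_b), rep(1, n_unl_b))
    pu_risk(risk_components(lg, lb), cfg)
  }, numeric(1))
  mc_se <- sd(vals) / sqrt(n_b)
  expect_lt(abs(mean(vals) - supervised), 3 * mc_se)
})
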