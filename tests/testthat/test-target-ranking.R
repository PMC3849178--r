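# pulse force used across GP fixtures: rises to its peak by 2 h
pulse <- function(t, a = 3) a * (t / 2) * exp(1 - t / 2)

# fine-grid trapezoidal solution of dx/dt = B + S f - D x
ode_traj <- function(t, B, S, D, x0, force, n = 2001) {
  vapply(t, function(tt) {
    base <- B / D + (x0 - B / D) * exp(-D * tt)
    if (tt == 0) return(base)
    u <- seq(0, tt, length.out = n)
    g <- exp(-D * (tt - u)) * force(u)
    base + S * sum(diff(u) * (head(g, -1) + tail(g, -1)) / 2)
  }, 0)
}

test_that("sim_kernel matches the double-quadrature oracle", {
  cases <- list(c(t1 = 2, t2 = 4, Dj = 0.5, Dk = 0.5, l = 2),
                c(t1 = 1, t2 = 1, Dj = 0.3, Dk = 1.2, l = 1),
                c(t1 = 8, t2 = 2, Dj = 1.5, Dk = 0.8, l = 4),
                c(t1 = 3, t2 = 6, Dj = 0.1, Dk = 0.1, l = 2))
  for (cs in cases) {
    a <- sim_kernel(cs["t1"], cs["t2"], list(S = 1, D = cs[["Dj"]]),
                    list(S = 1.5, D = cs[["Dk"]]), cs[["l"]])
    q <- quad_sim_cov(cs[["t1"]], cs[["t2"]], cs[["Dj"]], cs[["Dk"]],
                      1, 1.5, cs[["l"]])
    expect_equal(as.numeric(a), q, tolerance = 1e-6)
  }
})

test_that("sim_kernel limits: no force, fast decay, bad hyperparameters", {
  expect_equal(as.numeric(sim_kernel(2, 4, list(S = 0, D = 1),
                                     list(S = 0, D = 1), 2)), 0)
  fast <- as.numeric(sim_kernel(3, 3, list(S = 1, D = 400),
                                list(S = 1, D = 400), 2))
  expect_lt(fast, 1e-4)
  expect_gte(fast, 0)
  expect_error(sim_kernel(1, 1, list(S = 1, D = -1), list(S = 1, D = 1), 2),
               "positive")
  expect_error(sim_kernel(1, 1, list(S = 1, D = 1), list(S = 1, D = 1), 0),
               "positive")
})

test_that("sim_kernel Gram matrices are symmetric positive semi-definite", {
  grids <- list(seq(0, 8, by = 0.5), c(0, 2, 4, 8), seq(0, 4, length.out = 7))
  hp <- list(c(D = 0.2, l = 1), c(D = 1, l = 2), c(D = 3, l = 4))
  for (tt in grids) {
    for (h in hp) {
      p <- list(S = 1.3, D = h[["D"]])
      K <- sim_kernel(tt, tt, p, p, h[["l"]])
      expect_equal(K, t(K), tolerance = 1e-9)
      ev <- eigen(K + diag(1e-8, nrow(K)), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_true(all(ev >= -1e-8))
    }
  }
})

test_that("ODE parameters are recovered on a dense low-noise fixture", {
  set.seed(2)
  B <- 1; S <- 2; D <- 0.8
  td <- seq(0, 8, length.out = 16)
  ytf <- pulse(td) + rnorm(16, 0, 0.05)
  yg <- ode_traj(td, B, S, D, x0 = B / D, pulse) + rnorm(16, 0, 0.05)
  fit <- fit_target(td, ytf, td, yg, "g")
  expect_true(fit$converged)
  expect_lt(abs(fit$params["S"] - S) / S, 0.2)
  expect_lt(abs(fit$params["D"] - D) / D, 0.2)
  expect_lt(abs(fit$params["B"] - B) / B, 0.2)
})

test_that("force-free and unidentifiable profiles score near zero", {
  set.seed(3)
  td <- rep(c(0, 2, 4, 8), each = 4)
  ytf <- pulse(td) + rnorm(16, 0, 0.25)
  scores <- vapply(1:3, function(s) {
    set.seed(10 + s)
    yflat <- 1.25 + rnorm(16, 0, 0.25)
    fit_target(td, ytf, td, yflat, "flat")$score
  }, 0)
  # the coupled model can claim a few nats from noise (two extra
  # effective parameters); scores stay within chi-square-scale slack of 0
  expect_lt(max(abs(scores)), 3)
  expect_lt(mean(abs(scores)), 1.5)
  # constant TF, constant gene: model unidentifiable, null-equivalent
  set.seed(20)
  ytf_const <- 5 + rnorm(16, 0, 0.05)
  yg_const <- 2 + rnorm(16, 0, 0.05)
  fit <- fit_target(td, ytf_const, td, yg_const, "const")
  expect_lt(abs(fit$score), 2)
})

test_that("likelihood ratio is non-negative up to optimizer tolerance", {
  set.seed(4)
  td <- rep(c(0, 2, 4, 8), each = 4)
  ytf <- pulse(td) + rnorm(16, 0, 0.25)
  for (i in 1:4) {
    yg <- ode_traj(td, 1, runif(1, 0.5, 3), runif(1, 0.3, 1.2), 1.5, pulse) +
      rnorm(16, 0, 0.25)
    fit <- fit_target(td, ytf, td, yg)
    expect_gt(fit$score, -0.5)
  }
})

test_that("score is invariant to constant shifts of the gene profile", {
  set.seed(5)
  td <- rep(c(0, 2, 4, 8), each = 4)
  ytf <- pulse(td) + rnorm(16, 0, 0.25)
  yg <- ode_traj(td, 1, 2, 0.8, 1.25, pulse) + rnorm(16, 0, 0.25)
  f1 <- fit_target(td, ytf, td, yg)
  f2 <- fit_target(td, ytf, td, yg + 3)
  expect_equal(f1$score, f2$score, tolerance = 0.5)
})

test_that("rank_genes orders a TF-duplicate gene into the top decile", {
  set.seed(6)
  cfg <- scenario_config(seed = 6, n_genes = 30, n_targets = 6)
  ex <- simulate_expression(cfg)
  # append a noisy duplicate of the TF profile itself
  vals <- rbind(ex$expr$values,
                dup_tf = ex$expr$values["TF", ] + rnorm(32, 0, 0.1))
  ex2 <- new_expr(vals, ex$expr$samples)
  rk <- rank_genes(ex2, "TF", "WKY")
  expect_s3_class(rk, "target_ranking")
  expect_lte(which(rk$gene_id == "dup_tf"), ceiling(nrow(rk) / 10))
  expect_error(rank_genes(ex2, "nope", "WKY"), "absent")
})
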