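test_that("mcmc_config enforces its invariants", {
  expect_error(mcmc_config(iterations = 100, burn_in = 100),
               class = "subsidydiet_error_invalid_input")
  expect_error(mcmc_config(thin = 0),
               class = "subsidydiet_error_invalid_input")
  cfg <- mcmc_config(1000, 100, 2, seed = 7)
  expect_s3_class(cfg, "mcmc_config")
})

test_that("a single source forces every draw to p = 1", {
  src <- two_sources()[1:2, ]
  cons <- tibble::tibble(cat_id = c("a", "b"), group = "g",
                         d13C = c(-24.1, -23.9), d15N = c(2.1, 1.9))
  post <- run_mixing_mcmc(cons, src, mcmc_config(2000, 200, 2, seed = 1))
  expect_true(all(post$draws$alpha == 1))
})

test_that("draws close the simplex to machine tolerance", {
  cons <- forward_simulate(
    c("forest animals" = 0.3, "farmland animals" = 0.3,
      "artificial resources" = 0.4),
    paper_sources(), 25, seed = 3, sigma = c(0.5, 0.5), group = "g"
  )
  post <- run_mixing_mcmc(cons, paper_sources(),
                          mcmc_config(4000, 500, 4, seed = 5))
  sums <- post$draws[["forest animals"]] +
    post$draws[["farmland animals"]] +
    post$draws[["artificial resources"]]
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(post$draws[["forest animals"]] >= 0))
  expect_true(all(post$summary$hdr_low >= 0 & post$summary$hdr_high <= 1))
})

test_that("with the likelihood disabled the sampler returns the Dirichlet prior", {
  cons <- tibble::tibble(cat_id = "a", group = "g", d13C = -20, d15N = 5)
  post <- run_mixing_mcmc(cons, paper_sources(),
                          mcmc_config(42000, 2000, 10, seed = 11),
                          prior_only = TRUE)
  for (k in c("forest animals", "farmland animals", "artificial resources")) {
    expect_equal(mean(post$draws[[k]]), 1 / 3, tolerance = 0.025)
    expect_equal(stats::var(post$draws[[k]]), 1 / 18, tolerance = 0.05)
  }
})

test_that("vanishing-variance posterior matches the linear-solve oracle", {
  srcs <- paper_sources()
  srcs$sd <- 1e-6
  srcs$tef_sd <- 1e-6
  p_true <- c("forest animals" = 0.5, "farmland animals" = 0.3,
              "artificial resources" = 0.2)
  sm <- subsidydiet:::source_matrices(subsidydiet:::check_sources(srcs))
  mix <- as.numeric(sm$mean %*% p_true[sm$names])
  cons <- tibble::tibble(cat_id = sprintf("c%d", 1:5), group = "g",
                         d13C = mix[1], d15N = mix[2])
  oracle <- solve_mixing_oracle(srcs, mix)
  post <- run_mixing_mcmc(cons, srcs, mcmc_config(20000, 5000, 5, seed = 2))
  for (k in names(oracle)) {
    est <- post$summary$mean[post$summary$source == k]
    expect_lt(abs(est - oracle[[k]]), 0.01)
  }
})

test_that("the posterior recovers simulated truths and is seed-reproducible", {
  p_true <- c("forest animals" = 0.25, "farmland animals" = 0.15,
              "artificial resources" = 0.6)
  cons <- forward_simulate(p_true, paper_sources(), 60, seed = 8,
                           sigma = c(0.3, 0.3), group = "g")
  cfg <- mcmc_config(10000, 2000, 5, seed = 21)
  post <- run_mixing_mcmc(cons, paper_sources(), cfg)
  for (k in names(p_true)) {
    row <- post$summary[post$summary$source == k, ]
    expect_true(p_true[[k]] > row$hdr_low - 0.05 &&
                  p_true[[k]] < row$hdr_high + 0.05)
  }
  post2 <- run_mixing_mcmc(cons, paper_sources(), cfg)
  expect_identical(post$draws, post2$draws)
})

test_that("hdr finds the shortest window, equal to a brute-force scan", {
  expect_equal(hdr(rep(3, 200)), c(3, 3))
  d <- as.numeric(1:100)
  expect_equal(diff(hdr(d, 0.95)), 94)
  # brute force over all windows on an irregular sample
  set.seed(13)
  v <- sort(c(rnorm(150), rnorm(60, 5)))
  m <- ceiling(0.9 * length(v))
  widths <- vapply(seq_len(length(v) - m + 1),
                   function(i) v[i + m - 1] - v[i], 0)
  got <- hdr(v, 0.9)
  expect_equal(diff(got), min(widths))
  expect_true(sum(v >= got[1] & v <= got[2]) >= m)
  # large normal sample: close to the closed-form central interval
  z <- stats::qnorm(seq(0.00005, 0.99995, length.out = 20000))
  expect_equal(hdr(z, 0.95), c(-1.96, 1.96), tolerance = 0.01)
  expect_error(hdr(rnorm(50)), class = "subsidydiet_error_invalid_input")
})

test_that("forward_simulate is deterministic and matches mixture moments", {
  p <- c("forest animals" = 1, "farmland animals" = 0,
         "artificial resources" = 0)
  srcs <- paper_sources()
  srcs$sd <- 0
  srcs$tef_sd <- 0
  cons <- forward_simulate(p, srcs, 10, seed = 1)
  expect_true(all(cons$d13C == -24.8 + 2.3))
  expect_true(all(cons$d15N == 1.6 + 2.8))

  p2 <- c("forest animals" = 0.2, "farmland animals" = 0.3,
          "artificial resources" = 0.5)
  big <- forward_simulate(p2, paper_sources(), 1e5, seed = 2,
                          sigma = c(0.2, 0.2))
  sm <- subsidydiet:::source_matrices(paper_sources())
  mu <- as.numeric(sm$mean %*% p2)
  v <- as.numeric(sm$var %*% p2^2) + 0.04
  expect_lt(abs(mean(big$d13C) - mu[1]), 3 * sqrt(v[1] / 1e5))
  expect_lt(abs(mean(big$d15N) - mu[2]), 3 * sqrt(v[2] / 1e5))
  expect_identical(big, forward_simulate(p2, paper_sources(), 1e5, seed = 2,
                                         sigma = c(0.2, 0.2)))
  expect_error(forward_simulate(c(0.5, 0.2), paper_sources(), 5, 1),
               class = "subsidydiet_error_invalid_input")
})

test_that("one-way ANOVA matches a sum-of-squares oracle and the field df", {
  set.seed(17)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), times = c(8, 6, 7)),
    y = rnorm(21) + rep(c(0, 1, 0.5), times = c(8, 6, 7))
  )
  res <- group_summary_anova(d, "y", "g")
  # brute-force mean squares
  grand <- mean(d$y)
  ssb <- sum(tapply(d$y, d$g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(d$y, d$g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / (21 - 3))
  expect_equal(res$anova$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(nrow(res$tukey), 3)

  # all-equal values give F = 0
  d0 <- tibble::tibble(g = rep(c("a", "b"), each = 4), y = 5)
  expect_equal(group_summary_anova(d0, "y", "g")$anova$statistic, 0)

  # group sizes 189/52/9 give df (2, 247)
  d2 <- tibble::tibble(
    g = rep(c("feral", "stray", "indoor"), times = c(189, 52, 9)),
    y = rnorm(250)
  )
  res2 <- group_summary_anova(d2, "y", "g")
  expect_equal(c(res2$anova$df1, res2$anova$df2), c(2, 247))
})
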