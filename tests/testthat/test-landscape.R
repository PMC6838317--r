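square_grid <- function(n = 40, cell = 10, class = "forest") {
  centers <- (seq_len(n) - 0.5) * cell
  g <- expand.grid(x = centers, y = centers)
  tibble::tibble(x = g$x, y = g$y, class = class)
}

test_that("buffer coverage handles uniform, split, and empty cases", {
  lu <- square_grid()
  site <- tibble::tibble(site_id = "s1", x = 200, y = 200)
  cov <- buffer_coverage(site, lu, radii = 100)
  expect_equal(cov$forest_100, 1)
  expect_equal(cov$residential_100, 0)
  expect_equal(cov$building_density_100, 0)

  # vertical half-plane boundary through the site: half forest
  lu2 <- lu
  lu2$class[lu2$x > 200] <- "farmland"
  cov2 <- buffer_coverage(site, lu2, radii = 100)
  expect_equal(cov2$forest_100, 0.5, tolerance = 0.05)
  expect_equal(cov2$farmland_100, 0.5, tolerance = 0.05)

  b <- tibble::tibble(x = c(150, 205, 600), y = c(150, 205, 600))
  cov3 <- buffer_coverage(site, lu, b, radii = 100)
  expect_equal(cov3$building_density_100, 2 / (pi * 100^2 / 1e6))

  expect_error(
    buffer_coverage(tibble::tibble(site_id = "out", x = 1e5, y = 0), lu,
                    radii = 100),
    class = "subsidydiet_error_invalid_input"
  )
})

test_that("arcsine square-root transform maps the unit interval to radians", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.5), pi / 4)
  expect_equal(arcsine_sqrt(1 + 1e-10), pi / 2)
  expect_error(arcsine_sqrt(1.2), class = "subsidydiet_error_invalid_input")
})

test_that("factor analysis recovers a planted two-factor structure", {
  set.seed(5)
  n <- 300
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(
    resid_cov = 0.9 * f1, build = 0.85 * f1,
    forest = -0.9 * f2, farm = 0.8 * f2
  ) + matrix(rnorm(n * 4, 0, 0.4), n)
  fa <- factor_analysis(x)
  expect_equal(fa$parallel$n_recommended, 2)
  expect_true(all(fa$communalities >= 0 & fa$communalities <= 1))
  # congruence with the planted loadings, up to sign/permutation
  planted <- cbind(c(0.9, 0.85, 0, 0), c(0, 0, -0.9, 0.8))
  congr <- abs(crossprod(
    apply(planted, 2, function(v) v / sqrt(sum(v^2))),
    apply(fa$loadings, 2, function(v) v / sqrt(sum(v^2)))
  ))
  expect_true(all(apply(congr, 1, max) > 0.95))
  # variables sharing a latent driver load together with the same sign
  j <- which.max(abs(fa$loadings["resid_cov", ]))
  expect_equal(sign(fa$loadings["resid_cov", j]),
               sign(fa$loadings["build", j]))
  # orthogonal factors: promax is close to varimax
  fav <- factor_analysis(x, rotation = "varimax")
  expect_lt(max(abs(abs(fa$loadings) - abs(fav$loadings))), 0.1)
  expect_error(factor_analysis(x[, 1:2]),
               class = "subsidydiet_error_invalid_input")
})

test_that("Delaunay edges equal the brute-force circumcircle oracle", {
  set.seed(7)
  for (n in c(5, 12, 30)) {
    xy <- cbind(runif(n), runif(n)) * 1000
    got <- delaunay_edges(xy)
    want <- delaunay_brute_oracle(xy)
    expect_setequal(edge_key(got), edge_key(want))
  }
  # collinear fallback: chain graph
  line <- cbind(1:5, 2 * (1:5))
  ed <- delaunay_edges(line)
  expect_equal(nrow(ed), 4)
  deg <- tabulate(c(ed), nbins = 5)
  expect_equal(sort(deg), c(1, 1, 2, 2, 2))
})

test_that("MEM basis matches a hand-built eigendecomposition", {
  # four sites, general position (square breaks cocircular ties arbitrarily)
  xy <- tibble::tibble(x = c(0, 100, 110, 5), y = c(0, 5, 105, 95))
  basis <- mem_construct(xy)
  W <- matrix(0, 4, 4)
  ed <- delaunay_brute_oracle(as.matrix(xy))
  W[ed] <- 1; W[ed[, 2:1]] <- 1
  H <- diag(4) - 1 / 4
  eig <- eigen(H %*% W %*% H, symmetric = TRUE)
  keep <- abs(eig$values) > 1e-9
  expect_equal(basis$values, eig$values[keep], tolerance = 1e-10)
  for (j in seq_along(basis$values)) {
    v <- eig$vectors[, which(keep)[j]]
    got <- basis$vectors[, j]
    expect_equal(abs(got), abs(v), tolerance = 1e-9)
  }
  # sign convention and determinism
  basis2 <- mem_construct(xy)
  expect_identical(basis$vectors, basis2$vectors)
  first_nz <- apply(basis$vectors, 2, function(v) v[abs(v) > 1e-10][1])
  expect_true(all(first_nz > 0))
})

test_that("MEM vectors are centered, orthogonal, and at most n-1", {
  set.seed(9)
  sites <- tibble::tibble(x = runif(25) * 1000, y = runif(25) * 1000)
  basis <- mem_construct(sites)
  expect_lte(ncol(basis$vectors), 24)
  expect_true(all(abs(colMeans(basis$vectors)) < 1e-10))
  g <- crossprod(basis$vectors)
  expect_true(max(abs(g - diag(ncol(basis$vectors)))) < 1e-10)
  expect_error(mem_construct(tibble::tibble(x = c(0, 0, 1), y = c(0, 0, 1))),
               class = "subsidydiet_error_invalid_input")
  jit <- mem_construct(tibble::tibble(x = c(0, 0, 1, 2), y = c(0, 0, 1, 0)),
                       duplicates = "jitter")
  expect_s3_class(jit, "mem_basis")
})

test_that("MEM selection finds planted structure and respects the null", {
  set.seed(21)
  sites <- tibble::tibble(x = runif(40) * 1000, y = runif(40) * 1000)
  basis <- mem_construct(sites)
  # planted signal on MEM3
  hits <- 0
  for (r in 1:20) {
    y <- 2 * basis$vectors[, 3] + rnorm(40, 0, 0.3)
    sel <- mem_select(basis, data.frame(y = y), k_max = 10)
    if (sel$j_max >= 3) hits <- hits + 1
  }
  expect_gte(hits, 18)
  # white-noise responses: retention count follows the alpha level
  set.seed(22)
  n_sig <- 0; n_tests <- 0
  for (r in 1:30) {
    y <- rnorm(40)
    sel <- mem_select(basis, data.frame(y = y), k_max = 10)
    n_sig <- n_sig + sum(sel$tests$p_value < 0.05)
    n_tests <- n_tests + nrow(sel$tests)
  }
  expect_lt(abs(n_sig / n_tests - 0.05), 0.04)
  # no significant MEM retains none
  sel0 <- mem_select(basis, data.frame(y = rep(c(1, 2), 20)), k_max = 2,
                     alpha = 1e-12)
  expect_equal(sel0$retained, character(0))
})

test_that("retained MEMs absorb spatially autocorrelated residuals", {
  set.seed(31)
  sites <- tibble::tibble(x = runif(50) * 1000, y = runif(50) * 1000)
  basis <- mem_construct(sites)
  W <- matrix(0, 50, 50)
  W[basis$edges] <- 1; W[basis$edges[, 2:1]] <- 1
  reduced <- 0
  for (r in 1:25) {
    y <- basis$vectors[, 1:3] %*% c(1.5, 1, 0.8) + rnorm(50, 0, 0.4)
    y <- as.numeric(y)
    i_raw <- moran_i(resid(lm(y ~ 1)), W)
    i_mem <- moran_i(resid(lm(y ~ basis$vectors[, 1:6])), W)
    if (abs(i_mem) < abs(i_raw)) reduced <- reduced + 1
  }
  expect_gte(reduced / 25, 0.8)
})

test_that("AICc model averaging obeys its algebraic contracts", {
  set.seed(41)
  n <- 80
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 1 + 0.9 * d$a + rnorm(n, 0, 0.5)

  av <- fit_and_average(d, "y", c("a", "b", "c"))
  expect_equal(sum(av$models$weight, na.rm = TRUE), 1)
  expect_equal(av$n_models, 8)
  # AICc equals the brute-force formula for every candidate
  for (i in seq_len(nrow(av$models))) {
    tt <- av$models$terms[i]
    tt <- if (tt == "(intercept only)") character(0) else
      strsplit(tt, " \\+ ")[[1]]
    fit <- lm(subsidydiet:::build_formula("y", tt), data = d)
    k <- length(coef(fit)) + 1
    rss <- sum(resid(fit)^2)
    expect_equal(av$models$AICc[i],
                 n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                 tolerance = 1e-10)
  }
  # single candidate model: averaged estimates equal its OLS fit
  av1 <- fit_and_average(d, "y", "a")
  keep <- av1$models$delta < 2
  if (sum(keep) == 1) {
    ols <- coef(lm(y ~ a, data = d))
    expect_equal(av1$coefficients$estimate[av1$coefficients$term == "a"],
                 unname(ols["a"]))
  }
  # invariance to candidate order
  av_perm <- fit_and_average(d, "y", c("c", "a", "b"))
  ord <- match(av$coefficients$term, av_perm$coefficients$term)
  expect_equal(av$coefficients$estimate, av_perm$coefficients$estimate[ord],
               tolerance = 1e-12)
  # recovery: true coefficient within 2 adjusted SE
  row <- av$coefficients[av$coefficients$term == "a", ]
  expect_lt(abs(row$estimate - 0.9), 2 * row$std_error)
  expect_error(
    fit_and_average(dplyr::mutate(d, dup = a), "y", c("a", "dup")),
    class = "subsidydiet_error_invalid_input"
  )
})
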