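#' Land-use coverage and building density around capture sites
#'
#' For each site and buffer radius, the fraction of the disc covered by
#' each land-use class is the fraction of grid cells whose center lies
#' within the radius, and building density is the number of building
#' points within the disc per square kilometer.
#'
#' @param sites Data frame with `x`, `y` (planar meters) and an id column
#'   (`cat_id` or `site_id`).
#' @param landuse Gridded land-use layer: data frame `x`, `y`, `class`
#'   (regular grid of cell centers; classes typically `forest`,
#'   `residential`, `farmland`).
#' @param buildings Optional data frame of building points (`x`, `y`).
#' @param radii Buffer radii in meters.
#' @param classes Land-use classes to report (others still count toward
#'   the disc area).
#' @return Tibble: id column, `x`, `y`, then `<class>_<radius>` coverage
#'   fractions and `building_density_<radius>` (per km^2).
#' @export
buffer_coverage <- function(sites, landuse, buildings = NULL,
                            radii = c(100, 200, 500),
                            classes = c("forest", "residential", "farmland")) {
  stopifnot(all(c("x", "y") %in% names(sites)),
            all(c("x", "y", "class") %in% names(landuse)))
  id_col <- intersect(c("cat_id", "site_id"), names(sites))[1]
  if (is.na(id_col)) {
    sites$site_id <- sprintf("site_%03d", seq_len(nrow(sites)))
    id_col <- "site_id"
  }
  # grid resolution (smallest positive spacing on each axis)
  res_axis <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2) return(Inf)
    min(diff(u))
  }
  cell <- max(res_axis(landuse$x), res_axis(landuse$y))
  ext <- c(range(landuse$x), range(landuse$y)) + c(-1, 1, -1, 1) * cell / 2
  outside <- sites$x < ext[1] | sites$x > ext[2] |
    sites$y < ext[3] | sites$y > ext[4]
  if (any(outside)) {
    abort_invalid(paste0(
      "Sites outside the land-use layer extent: ",
      paste(sites[[id_col]][outside], collapse = ", ")
    ))
  }

  out <- tibble::tibble(
    !!id_col := sites[[id_col]], x = sites$x, y = sites$y
  )
  for (r in radii) {
    cov <- matrix(0, nrow = nrow(sites), ncol = length(classes),
                  dimnames = list(NULL, classes))
    dens <- numeric(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      d2 <- (landuse$x - sites$x[i])^2 + (landuse$y - sites$y[i])^2
      inside <- d2 <= r^2
      n_in <- sum(inside)
      if (n_in == 0) {
        abort_invalid(paste0(
          "Buffer of radius ", r, " m around site ", sites[[id_col]][i],
          " contains no land-use cells; the grid is too coarse."
        ))
      }
      cls <- landuse$class[inside]
      for (k in classes) cov[i, k] <- sum(cls == k) / n_in
      if (!is.null(buildings)) {
        bd2 <- (buildings$x - sites$x[i])^2 + (buildings$y - sites$y[i])^2
        dens[i] <- sum(bd2 <= r^2) / (pi * r^2 / 1e6)
      }
    }
    for (k in classes) out[[paste0(k, "_", r)]] <- as.numeric(cov[, k])
    out[[paste0("building_density_", r)]] <- as.numeric(dens)
  }
  out
}

#' Exploratory factor analysis of landscape covariates
#'
#' Maximum-likelihood factor extraction with Promax (oblique) rotation and
#' regression-method factor scores, plus a parallel analysis (eigenvalues
#' of the observed correlation matrix against random-data eigenvalues)
#' reporting the recommended number of factors.
#'
#' @param covariates Data frame or matrix of numeric site covariates
#'   (rows = sites); more rows than columns required.
#' @param n_factors Number of factors extracted (default 2).
#' @param rotation `"promax"` (power 4) or `"varimax"`.
#' @param n_random Random data sets used by the parallel analysis.
#' @param seed Seed for the parallel analysis randomization.
#' @return A `factor_solution`: `loadings` (variables x factors), `scores`
#'   tibble (`Factor1`, `Factor2`, ...), `communalities`, `uniquenesses`,
#'   `parallel` (observed eigenvalues, random 95th percentiles,
#'   `n_recommended`), `rotation`.
#' @export
factor_analysis <- function(covariates, n_factors = 2, rotation = "promax",
                            n_random = 100, seed = 1) {
  x <- as.matrix(covariates)
  if (!is.numeric(x)) abort_invalid("Covariates must be numeric.")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < n_factors + 1) {
    abort_invalid("Need at least n_factors + 1 covariates.")
  }
  if (nrow(x) <= ncol(x)) abort_invalid("Need more sites than covariates.")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort_invalid(paste0(
      "Constant covariate(s): ",
      paste(colnames(x)[sds == 0], collapse = ", ")
    ))
  }
  cm <- stats::cor(x)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    rlang::abort(
      paste0(
        "Correlation matrix is not positive definite ",
        "(min eigenvalue ", format(min(ev)), ", condition number ",
        format(max(ev) / max(min(ev), 1e-300)), ")."
      ),
      class = "subsidydiet_error_invalid_input"
    )
  }
  parallel <- parallel_analysis(nrow(x), ncol(x), ev, n_random, seed)

  fa <- ml_factor_extract(cm, n_factors)
  load_un <- fa$loadings
  if (rotation == "promax") {
    rot <- stats::promax(load_un, m = 4)
  } else if (rotation == "varimax") {
    rot <- stats::varimax(load_un)
  } else {
    abort_invalid("`rotation` must be 'promax' or 'varimax'.")
  }
  loadings <- unclass(rot$loadings)
  colnames(loadings) <- paste0("Factor", seq_len(n_factors))
  # Thomson regression scores: Z R^-1 S with S the structure matrix
  # (pattern x factor correlation; Phi = I for orthogonal rotations)
  phi <- if (rotation == "promax") {
    solve(crossprod(rot$rotmat))
  } else {
    diag(n_factors)
  }
  z <- scale(x)
  scores <- z %*% solve(cm) %*% (loadings %*% phi)
  colnames(scores) <- colnames(loadings)

  structure(
    list(
      loadings = loadings,
      scores = tibble::as_tibble(scores),
      communalities = 1 - fa$uniquenesses,
      uniquenesses = fa$uniquenesses,
      parallel = parallel,
      rotation = rotation,
      n_factors = n_factors
    ),
    class = "factor_solution"
  )
}

# Maximum-likelihood factor extraction: minimize the ML discrepancy
# F(psi) = sum_{j>k} (lambda_j - log lambda_j - 1) over uniquenesses psi,
# with lambda the eigenvalues of psi^-1/2 R psi^-1/2. Unlike factanal()
# no degrees-of-freedom gate is applied, so k = 2 factors can be
# extracted from as few as 4 variables (the landscape case).
ml_factor_extract <- function(cm, k) {
  p <- ncol(cm)
  if (k >= p) abort_invalid("Need more variables than factors.")
  objective <- function(lpsi) {
    psi <- exp(lpsi)
    d <- 1 / sqrt(psi)
    ev <- eigen(outer(d, d) * cm, symmetric = TRUE, only.values = TRUE)$values
    tail_ev <- pmax(ev[(k + 1):p], 1e-12)
    sum(tail_ev - log(tail_ev) - 1)
  }
  start <- log(pmax(1 - 0.5 * diag(solve(cm))^-1, 0.1))
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = log(0.005), upper = log(1),
                      control = list(maxit = 500))
  psi <- exp(opt$par)
  d <- 1 / sqrt(psi)
  eig <- eigen(outer(d, d) * cm, symmetric = TRUE)
  lam <- sqrt(pmax(eig$values[seq_len(k)] - 1, 0))
  loadings <- sweep(eig$vectors[, seq_len(k), drop = FALSE] %*% diag(lam, k),
                    1, sqrt(psi), `*`)
  # sign convention: dominant loading of each factor positive
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
    }
  }
  rownames(loadings) <- rownames(cm)
  list(loadings = loadings,
       uniquenesses = stats::setNames(pmin(pmax(
         1 - rowSums(loadings^2), 0), 1), rownames(cm)),
       criterion = opt$value, converged = opt$convergence == 0)
}

parallel_analysis <- function(n, p, observed_ev, n_random = 100, seed = 1) {
  set.seed(seed)
  rand <- matrix(0, nrow = n_random, ncol = p)
  for (b in seq_len(n_random)) {
    r <- matrix(stats::rnorm(n * p), n, p)
    rand[b, ] <- eigen(stats::cor(r), symmetric = TRUE,
                       only.values = TRUE)$values
  }
  q95 <- apply(rand, 2, stats::quantile, probs = 0.95)
  list(
    observed = observed_ev,
    random_q95 = q95,
    n_recommended = sum(observed_ev > q95)
  )
}

#' @method print factor_solution
#' @export
print.factor_solution <- function(x, ...) {
  cat("ML factor analysis,", x$n_factors, "factors,", x$rotation,
      "rotation\n")
  cat("Parallel analysis recommends", x$parallel$n_recommended, "factor(s)\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @method tidy factor_solution
#' @export
tidy.factor_solution <- function(x, ...) {
  tibble::tibble(
    variable = rep(rownames(x$loadings), ncol(x$loadings)),
    factor = rep(colnames(x$loadings), each = nrow(x$loadings)),
    loading = as.vector(x$loadings)
  )
}

#' Moran's eigenvector maps from a Delaunay connectivity graph
#'
#' Builds the binary spatial connectivity matrix W of the sites' Delaunay
#' triangulation, doubly centers it, and eigen-decomposes; the
#' eigenvectors, ordered by decreasing eigenvalue, are MEM1, MEM2, ...
#' (large positive eigenvalues = broad spatial structure). Eigenvectors of
#' (numerically) zero eigenvalue, including the one absorbed by centering,
#' are dropped. Sign convention: the first nonzero loading of each vector
#' is positive.
#'
#' @param sites Data frame with `x`, `y` planar coordinates (meters).
#' @param duplicates `"error"` (default) or `"jitter"` (tiny uniform
#'   perturbation, deterministic in the coordinates).
#' @return A `mem_basis`: `vectors` (sites x m matrix, columns MEM1..m),
#'   `values` (eigenvalues), `edges` (Delaunay edge indices), `xy`.
#' @export
mem_construct <- function(sites, duplicates = c("error", "jitter")) {
  duplicates <- match.arg(duplicates)
  xy <- as.matrix(sites[, c("x", "y")])
  n <- nrow(xy)
  if (n < 3) abort_invalid("At least 3 sites are required.")
  if (anyDuplicated(xy)) {
    if (duplicates == "error") {
      abort_invalid("Duplicate site coordinates; set duplicates = 'jitter'.")
    }
    span <- max(apply(xy, 2, function(v) diff(range(v))), 1)
    dup <- which(duplicated(xy))
    # deterministic jitter derived from row index
    xy[dup, ] <- xy[dup, ] +
      cbind(sin(dup * 12.9898), cos(dup * 78.233)) * span * 1e-6
  }
  edges <- delaunay_edges(xy)
  W <- matrix(0, n, n)
  W[edges] <- 1
  W[edges[, c(2, 1), drop = FALSE]] <- 1
  H <- diag(n) - matrix(1 / n, n, n)
  M <- H %*% W %*% H
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  keep <- which(abs(eig$values) > tol)
  vec <- eig$vectors[, keep, drop = FALSE]
  # fixed sign: first loading of non-negligible magnitude positive
  for (j in seq_len(ncol(vec))) {
    nz <- which(abs(vec[, j]) > 1e-10)[1]
    if (!is.na(nz) && vec[nz, j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("MEM", seq_len(ncol(vec)))
  structure(
    list(vectors = vec, values = eig$values[keep], edges = edges, xy = xy),
    class = "mem_basis"
  )
}

#' Retain the leading MEMs significantly associated with the responses
#'
#' Each of MEM1..k_max is tested one at a time as the sole predictor of
#' each response (OLS t-test at `alpha`); the retained set is MEM1..J
#' where J is the largest significant index over all responses.
#'
#' @param basis A [mem_construct()] result.
#' @param responses Data frame or matrix of response variables (rows
#'   matching the basis sites).
#' @param k_max Largest MEM index considered.
#' @param alpha Significance level.
#' @return List: `retained` (character vector `MEM1`..`MEMJ`, possibly
#'   empty), `j_max`, `tests` tibble (response, mem, p_value).
#' @export
mem_select <- function(basis, responses, k_max = 10, alpha = 0.05) {
  stopifnot(inherits(basis, "mem_basis"))
  responses <- as.data.frame(responses)
  m <- min(k_max, ncol(basis$vectors))
  tests <- purrr::map(names(responses), function(rn) {
    y <- responses[[rn]]
    purrr::map(seq_len(m), function(k) {
      fit <- stats::lm(y ~ basis$vectors[, k])
      p <- summary(fit)$coefficients[2, 4]
      tibble::tibble(response = rn, mem = k, p_value = p)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  sig <- tests$mem[tests$p_value < alpha]
  j <- if (length(sig) > 0) max(sig) else 0L
  list(
    retained = if (j > 0) paste0("MEM", seq_len(j)) else character(0),
    j_max = j,
    tests = tests
  )
}

#' Moran's I spatial autocorrelation statistic
#'
#' @param x Numeric vector of site values.
#' @param W Symmetric connectivity/weight matrix.
#' @return Moran's I.
#' @export
moran_i <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  s0 <- sum(W)
  (n / s0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

#' Arcsine square-root transform of a proportion
#'
#' Variance-stabilizing transform applied to dietary proportions before
#' Gaussian modelling: asin(sqrt(p)), in radians.
#'
#' @param p Proportions in [0, 1]; values straying outside by less than
#'   1e-9 are clipped.
#' @return Radians in [0, pi/2].
#' @export
arcsine_sqrt <- function(p) {
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE)) {
    abort_invalid("Proportions must lie in [0, 1].")
  }
  asin(sqrt(pmin(pmax(p, 0), 1)))
}
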