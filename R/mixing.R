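#' MCMC configuration for the mixing model
#'
#' Defaults follow the published schedule: 50,000 iterations, the first
#' 5,000 discarded, thinning by 10.
#'
#' @param iterations Total Metropolis iterations.
#' @param burn_in Iterations discarded (proposal scale adapts only here).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer seed; every run is reproducible given the seed.
#' @param proposal_scale Initial random-walk standard deviation.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 50000, burn_in = 5000, thin = 10,
                        seed = 1, proposal_scale = 0.15) {
  if (!(iterations > burn_in && burn_in >= 0)) {
    abort_invalid("`iterations` must exceed `burn_in` (>= 0).")
  }
  if (thin < 1) abort_invalid("`thin` must be >= 1.")
  if (proposal_scale <= 0) abort_invalid("`proposal_scale` must be positive.")
  structure(
    list(
      iterations = as.integer(iterations), burn_in = as.integer(burn_in),
      thin = as.integer(thin), seed = as.integer(seed),
      proposal_scale = proposal_scale
    ),
    class = "mcmc_config"
  )
}

check_sources <- function(sources) {
  need <- c("name", "isotope", "mean", "sd", "tef_mean", "tef_sd")
  if (!is.data.frame(sources) || !all(need %in% names(sources))) {
    abort_invalid(paste0(
      "`sources` needs columns: ", paste(need, collapse = ", ")
    ))
  }
  isos <- c("d13C", "d15N")
  sources <- dplyr::filter(sources, .data$isotope %in% isos)
  tallies <- table(sources$name, sources$isotope)
  if (!all(tallies == 1)) {
    abort_invalid("Every source needs exactly one row per isotope (d13C, d15N).")
  }
  if (any(sources$sd < 0) || any(sources$tef_sd < 0)) {
    abort_invalid("Source and TEF standard deviations must be >= 0.")
  }
  sources
}

# J x K matrices of TEF-corrected source means and combined variances
source_matrices <- function(sources) {
  src_names <- unique(sources$name)
  isos <- c("d13C", "d15N")
  madj <- vadj <- matrix(0, nrow = 2, ncol = length(src_names),
                         dimnames = list(isos, src_names))
  for (j in isos) {
    for (k in src_names) {
      row <- sources[sources$isotope == j & sources$name == k, ]
      madj[j, k] <- row$mean + row$tef_mean
      vadj[j, k] <- row$sd^2 + row$tef_sd^2
    }
  }
  list(names = src_names, mean = madj, var = vadj)
}

#' Bayesian stable-isotope mixing model (Dirichlet prior, Metropolis MCMC)
#'
#' Estimates, per consumer group, the proportions in which K dietary
#' sources are mixed, from two isotopes. The model for consumer \eqn{i} of
#' a group, isotope \eqn{j}:
#' \deqn{x_{ij} \sim N\!\Big(\sum_k p_k(\mu_{jk}+c_{jk}),\;
#'       \sum_k p_k^2(\omega_{jk}^2+\tau_{jk}^2) + \sigma_j^2\Big)}
#' with source signatures \eqn{\mu \pm \omega}, trophic enrichment factors
#' \eqn{c \pm \tau}, diet proportions \eqn{p} on the simplex with a flat
#' Dirichlet(1,...,1) prior, and residual SDs \eqn{\sigma_j \sim U(0, 20)}.
#' Source and TEF uncertainty enter through the marginalized variance term:
#' this matches the first two moments of sampling latent source values per
#' consumer and keeps the sampler small. Groups share sources and TEFs but
#' get independent proportions and residual SDs.
#'
#' Sampling is random-walk Metropolis on the additive log-ratio transform
#' of \eqn{p} (with its Jacobian) jointly with \eqn{\log\sigma_j}; the
#' proposal scale adapts during burn-in towards 20-40\% acceptance.
#'
#' @param consumers Data frame: `cat_id`, `group`, `d13C`, `d15N`.
#' @param sources Data frame: `name`, `isotope`, `mean`, `sd`, `tef_mean`,
#'   `tef_sd` (one row per source x isotope).
#' @param config An [mcmc_config()].
#' @param groups Groups to fit (default: all groups present).
#' @param hdr_mass Posterior mass of the reported highest-density regions.
#' @param prior_only If `TRUE` the likelihood is switched off and the
#'   sampler targets the prior (used for validation).
#' @return A `diet_posterior` object: `draws` (tibble: group, draw, one
#'   column per source proportion, `sigma_d13C`, `sigma_d15N`), `summary`
#'   (group, source, mean, sd, hdr_low, hdr_high), `diagnostics` (group,
#'   acceptance rate, min effective sample size), plus the inputs.
#' @examples
#' srcs <- tibble::tibble(
#'   name = rep(c("a", "b"), each = 2), isotope = rep(c("d13C", "d15N"), 2),
#'   mean = c(-24, 2, -18, 6), sd = 0.5, tef_mean = 0, tef_sd = 0
#' )
#' cons <- tibble::tibble(cat_id = "c1", group = "feral", d13C = -21, d15N = 4)
#' run_mixing_mcmc(cons, srcs, mcmc_config(2000, 500, 5, seed = 1))
#' @export
run_mixing_mcmc <- function(consumers, sources, config = mcmc_config(),
                            groups = NULL, hdr_mass = 0.95,
                            prior_only = FALSE) {
  stopifnot(inherits(config, "mcmc_config"))
  need <- c("group", "d13C", "d15N")
  if (!is.data.frame(consumers) || !all(need %in% names(consumers))) {
    abort_invalid("`consumers` needs columns group, d13C, d15N.")
  }
  if (any(!is.finite(consumers$d13C)) || any(!is.finite(consumers$d15N))) {
    abort_invalid("Consumer isotope values must be finite.")
  }
  sources <- check_sources(sources)
  sm <- source_matrices(sources)
  if (is.null(groups)) groups <- unique(consumers$group)
  missing_g <- setdiff(groups, unique(consumers$group))
  if (length(missing_g) > 0) {
    abort_invalid(paste0("No consumers in group(s): ",
                         paste(missing_g, collapse = ", ")))
  }

  results <- purrr::imap(
    stats::setNames(groups, groups),
    function(g, gi) {
      x <- consumers[consumers$group == g, c("d13C", "d15N")]
      # independent, reproducible substream per group
      sub_seed <- as.integer(
        (as.numeric(config$seed) + 7919 * match(g, groups)) %% 2147483647
      )
      sample_group_posterior(
        as.matrix(x), sm, config, sub_seed, prior_only = prior_only
      )
    }
  )

  draws <- purrr::imap(results, function(r, g) {
    d <- tibble::as_tibble(r$draws)
    d$group <- g
    d$draw <- seq_len(nrow(d))
    d
  }) |>
    purrr::list_rbind() |>
    dplyr::relocate("group", "draw")

  summary <- purrr::map(sm$names, function(k) {
    draws |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        source = k,
        mean = mean(.data[[k]]),
        sd = stats::sd(.data[[k]]),
        hdr_low = hdr(.data[[k]], hdr_mass)[1],
        hdr_high = hdr(.data[[k]], hdr_mass)[2],
        .groups = "drop"
      )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$group, .data$source)

  diagnostics <- purrr::imap(results, function(r, g) {
    ess <- vapply(sm$names, function(k) eff_sample_size(r$draws[, k]), 0)
    tibble::tibble(
      group = g, acceptance = r$acceptance,
      ess_min = min(ess), n_draws = nrow(r$draws),
      failed = r$acceptance == 0
    )
  }) |> purrr::list_rbind()

  structure(
    list(
      draws = draws, summary = summary, diagnostics = diagnostics,
      sources = sources, config = config, hdr_mass = hdr_mass,
      groups = groups
    ),
    class = "diet_posterior"
  )
}

# Metropolis sampler for one group. x: n x 2 matrix (d13C, d15N columns).
sample_group_posterior <- function(x, sm, config, seed, prior_only = FALSE,
                                   sigma_max = 20) {
  set.seed(seed)
  K <- length(sm$names)
  n <- nrow(x)
  # sufficient statistics per isotope
  s1 <- sum(x[, 1]); ss1 <- sum(x[, 1]^2)
  s2 <- sum(x[, 2]); ss2 <- sum(x[, 2]^2)
  m1 <- sm$mean[1, ]; v1 <- sm$var[1, ]
  m2 <- sm$mean[2, ]; v2 <- sm$var[2, ]

  log_target <- function(z, ls) {
    # p via additive log-ratio (last coordinate reference)
    e <- exp(c(z, 0))
    p <- e / sum(e)
    sig <- exp(ls)
    if (any(sig >= sigma_max)) return(-Inf)
    # flat Dirichlet prior x ALR Jacobian (prod p_k) x log-sigma Jacobian
    lp <- sum(log(p)) + sum(ls)
    if (!prior_only) {
      mu1 <- sum(p * m1); V1 <- sum(p^2 * v1) + sig[1]^2
      mu2 <- sum(p * m2); V2 <- sum(p^2 * v2) + sig[2]^2
      ll1 <- -0.5 * n * log(2 * pi * V1) -
        (ss1 - 2 * mu1 * s1 + n * mu1^2) / (2 * V1)
      ll2 <- -0.5 * n * log(2 * pi * V2) -
        (ss2 - 2 * mu2 * s2 + n * mu2^2) / (2 * V2)
      lp <- lp + ll1 + ll2
    }
    lp
  }

  # initialize proportions at the least-squares fit of the mean balance
  # and sigma at the sample SDs; the chain then explores from a sensible
  # point even when source variances are near zero
  z <- rep(0, K - 1)
  if (!prior_only && K > 1) {
    xbar <- colMeans(x)
    mean_fit <- function(zz) {
      e <- exp(c(zz, 0)); p <- e / sum(e)
      (xbar[1] - sum(p * m1))^2 + (xbar[2] - sum(p * m2))^2
    }
    z <- if (K == 2) {
      stats::optim(z, mean_fit, method = "Brent", lower = -20, upper = 20)$par
    } else {
      stats::optim(z, mean_fit, method = "Nelder-Mead")$par
    }
  }
  ls <- if (prior_only || nrow(x) < 2) c(0, 0) else {
    log(pmax(pmin(apply(x, 2, stats::sd), sigma_max * 0.9), 0.05))
  }
  cur <- log_target(z, ls)
  if (!is.finite(cur)) {
    z <- rep(0, K - 1); ls <- c(0, 0); cur <- log_target(z, ls)
  }
  # block-wise random walk with separate adapted scales
  scales <- c(p = config$proposal_scale, sigma = config$proposal_scale)
  accept_post <- 0L
  kept <- matrix(
    0.0,
    nrow = (config$iterations - config$burn_in) %/% config$thin,
    ncol = K + 2, dimnames = list(NULL, c(sm$names, "sigma_d13C", "sigma_d15N"))
  )
  krow <- 0L
  acc_window <- c(p = 0L, sigma = 0L)
  for (it in seq_len(config$iterations)) {
    if (K > 1) {
      z_new <- z + stats::rnorm(K - 1, 0, scales[["p"]])
      prop <- log_target(z_new, ls)
      if (is.finite(prop) && log(stats::runif(1)) < prop - cur) {
        z <- z_new; cur <- prop
        acc_window[["p"]] <- acc_window[["p"]] + 1L
        if (it > config$burn_in) accept_post <- accept_post + 1L
      }
    }
    ls_new <- ls + stats::rnorm(2, 0, scales[["sigma"]])
    prop <- log_target(z, ls_new)
    if (is.finite(prop) && log(stats::runif(1)) < prop - cur) {
      ls <- ls_new; cur <- prop
      acc_window[["sigma"]] <- acc_window[["sigma"]] + 1L
      if (it > config$burn_in) accept_post <- accept_post + 1L
    }
    # burn-in adaptation toward 20-40% acceptance per block
    if (it <= config$burn_in && it %% 50 == 0) {
      for (b in c("p", "sigma")) {
        rate <- acc_window[[b]] / 50
        if (rate < 0.20) scales[[b]] <- scales[[b]] * 0.8
        if (rate > 0.40) scales[[b]] <- scales[[b]] * 1.25
        acc_window[[b]] <- 0L
      }
    }
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
      krow <- krow + 1L
      e <- exp(c(z, 0))
      kept[krow, ] <- c(e / sum(e), exp(ls))
    }
  }
  n_post <- config$iterations - config$burn_in
  list(
    draws = kept[seq_len(krow), , drop = FALSE],
    acceptance = accept_post / (n_post * (1 + (K > 1))),
    final_scales = scales
  )
}

#' Highest-density region of a posterior sample
#'
#' The shortest contiguous interval containing the requested posterior
#' mass, found by scanning all windows of ceiling(mass * N) sorted draws.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @param mass Fraction of draws the interval must contain.
#' @return Length-2 numeric vector `(low, high)`.
#' @examples
#' hdr(rnorm(5000))
#' @export
hdr <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) < 100) {
    abort_invalid("At least 100 draws are required for an HDR.")
  }
  if (!(mass > 0 && mass < 1)) abort_invalid("`mass` must be in (0, 1).")
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  lo_idx <- seq_len(n - m + 1)
  widths <- s[lo_idx + m - 1] - s[lo_idx]
  i <- lo_idx[which.min(widths)]
  c(s[i], s[i + m - 1])
}

# effective sample size by initial positive autocorrelation truncation
eff_sample_size <- function(v) {
  n <- length(v)
  if (n < 10 || stats::sd(v) == 0) return(n)
  rho <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg) > 0) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' One-way ANOVA with Tukey HSD across groups
#'
#' Used to compare isotope signatures among consumer groups and among
#' candidate sources.
#'
#' @param data Data frame.
#' @param value Name of the numeric response column.
#' @param group Name of the grouping column.
#' @return List of class `isotope_anova`: `anova` (one-row tibble with F,
#'   df, p) and `tukey` (pairwise comparisons).
#' @export
group_summary_anova <- function(data, value, group) {
  v <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort_invalid("Need at least two groups.")
  if (any(table(g) < 1)) abort_invalid("Every group needs observations.")
  fit <- stats::aov(v ~ g)
  at <- suppressWarnings(stats::anova(fit))
  tk <- stats::TukeyHSD(fit)$g
  # degenerate case: no between-group variation => F defined as 0
  ssb <- at$`Sum Sq`[1]
  if (ssb <= 1e-12 * max(1, sum(v^2))) {
    at$`F value`[1] <- 0
    at$`Pr(>F)`[1] <- 1
  }
  structure(
    list(
      anova = tibble::tibble(
        statistic = at$`F value`[1],
        df1 = at$Df[1], df2 = at$Df[2],
        p_value = at$`Pr(>F)`[1]
      ),
      tukey = tibble::tibble(
        contrast = rownames(tk),
        estimate = tk[, "diff"],
        conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
        p_adj = tk[, "p adj"]
      ),
      value = value, group = group
    ),
    class = "isotope_anova"
  )
}

#' Simulate consumers from the mixing model
#'
#' Generative twin of the mixing likelihood: consumers are drawn from
#' \eqn{N(\sum_k p_k(\mu_{jk}+c_{jk}), \sum_k p_k^2(\omega_{jk}^2+\tau_{jk}^2)
#' + \sigma_j^2)} per isotope.
#'
#' @param p_true Named or ordered proportions over the sources (simplex).
#' @param sources As in [run_mixing_mcmc()].
#' @param n_consumers Number of consumers to draw.
#' @param seed Integer seed.
#' @param sigma Residual SDs per isotope (d13C, d15N).
#' @param group Group label stamped on the output.
#' @return Tibble: `cat_id`, `group`, `d13C`, `d15N`.
#' @export
forward_simulate <- function(p_true, sources, n_consumers, seed,
                             sigma = c(0, 0), group = "sim") {
  sources <- check_sources(sources)
  sm <- source_matrices(sources)
  K <- length(sm$names)
  if (length(p_true) != K || any(p_true < 0) ||
      abs(sum(p_true) - 1) > 1e-9) {
    abort_invalid("`p_true` must be a simplex point over the sources.")
  }
  if (!is.null(names(p_true))) p_true <- p_true[sm$names]
  set.seed(seed)
  mu <- as.numeric(sm$mean %*% p_true)
  v <- as.numeric(sm$var %*% p_true^2) + sigma^2
  tibble::tibble(
    cat_id = sprintf("%s_%04d", group, seq_len(n_consumers)),
    group = group,
    d13C = stats::rnorm(n_consumers, mu[1], sqrt(v[1])),
    d15N = stats::rnorm(n_consumers, mu[2], sqrt(v[2]))
  )
}

#' @method print diet_posterior
#' @export
print.diet_posterior <- function(x, ...) {
  cat("Bayesian mixing model posterior (",
      paste(x$groups, collapse = ", "), ")\n", sep = "")
  cat("  ", x$config$iterations, " iterations, burn-in ", x$config$burn_in,
      ", thin ", x$config$thin, ", seed ", x$config$seed, "\n", sep = "")
  s <- x$summary
  s$mean <- round(100 * s$mean, 1)
  s$hdr <- sprintf("%.1f-%.1f", 100 * x$summary$hdr_low, 100 * x$summary$hdr_high)
  print(dplyr::select(s, "group", "source",
                      `mean %` = "mean", `95% HDR` = "hdr"), ...)
  invisible(x)
}

#' @method tidy diet_posterior
#' @export
tidy.diet_posterior <- function(x, ...) x$summary

#' @method glance diet_posterior
#' @export
glance.diet_posterior <- function(x, ...) {
  dplyr::summarise(
    x$diagnostics,
    groups = dplyr::n(),
    acceptance = mean(.data$acceptance),
    ess_min = min(.data$ess_min),
    n_draws = sum(.data$n_draws)
  )
}
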