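#' All-subsets Gaussian GLM with AICc multimodel averaging
#'
#' Fits ordinary least squares (Gaussian identity-link GLM) models for
#' every subset of the candidate terms, ranks them by the small-sample
#' Akaike criterion
#' \deqn{AICc = n \log(RSS/n) + 2k + \frac{2k(k+1)}{n-k-1}}
#' (k counting the intercept and the residual variance), and averages the
#' coefficients of all models with \eqn{\Delta AICc <} `delta_max`. Full
#' averaging is used: a term absent from a model contributes a zero
#' estimate to the average. Adjusted standard errors follow the standard
#' multimodel formula \eqn{\sum_i w_i \sqrt{se_i^2 + (\beta_i -
#' \bar\beta)^2}}; z and p are Wald-normal.
#'
#' @param data Data frame with the response and all candidate terms.
#' @param response Name of the response column.
#' @param terms Character vector of candidate term names (columns of
#'   `data`; factors allowed).
#' @param delta_max Width of the averaging set (default 2).
#' @return An `averaged_model`: `coefficients` tibble (term, estimate,
#'   std_error, z, p_value, stars), `models` tibble (terms, k, AICc,
#'   delta, weight — weights renormalized over the averaging set, `NA`
#'   outside it), `response`, `n`, `n_models`.
#' @export
fit_and_average <- function(data, response, terms, delta_max = 2) {
  data <- as.data.frame(data)
  miss <- setdiff(c(response, terms), names(data))
  if (length(miss) > 0) {
    abort_invalid(paste0("Missing columns: ", paste(miss, collapse = ", ")))
  }
  data <- data[stats::complete.cases(data[c(response, terms)]), , drop = FALSE]
  n <- nrow(data)
  if (n <= length(terms) + 3) {
    abort_invalid("Too few complete cases for the global model.")
  }
  global <- stats::lm(build_formula(response, terms), data = data)
  if (any(is.na(stats::coef(global)))) {
    aliased <- names(stats::coef(global))[is.na(stats::coef(global))]
    abort_invalid(paste0(
      "Global model is rank deficient; aliased terms: ",
      paste(aliased, collapse = ", ")
    ))
  }

  t_count <- length(terms)
  subsets <- lapply(seq_len(2^t_count) - 1, function(mask) {
    terms[bitwAnd(mask, 2^(seq_len(t_count) - 1)) > 0]
  })
  fits <- lapply(subsets, function(tt) {
    fit <- stats::lm(build_formula(response, tt), data = data)
    rss <- sum(stats::residuals(fit)^2)
    k <- length(stats::coef(fit)) + 1  # + residual variance
    aicc <- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    list(terms = tt, fit = fit, k = k, aicc = aicc)
  })
  aicc <- vapply(fits, `[[`, 0, "aicc")
  delta <- aicc - min(aicc)
  in_set <- delta < delta_max
  w_raw <- exp(-delta[in_set] / 2)
  w <- w_raw / sum(w_raw)

  sel <- fits[in_set]
  coef_names <- unique(unlist(lapply(sel, function(f) names(stats::coef(f$fit)))))
  est <- se <- matrix(0, nrow = length(sel), ncol = length(coef_names),
                      dimnames = list(NULL, coef_names))
  for (i in seq_along(sel)) {
    cf <- summary(sel[[i]]$fit)$coefficients
    est[i, rownames(cf)] <- cf[, "Estimate"]
    se[i, rownames(cf)] <- cf[, "Std. Error"]
  }
  avg <- colSums(w * est)
  adj_se <- vapply(seq_along(coef_names), function(j) {
    sum(w * sqrt(se[, j]^2 + (est[, j] - avg[j])^2))
  }, 0)
  z <- ifelse(adj_se > 0, abs(avg) / adj_se, NA_real_)
  p <- 2 * stats::pnorm(-z)

  coefs <- tibble::tibble(
    term = coef_names,
    estimate = unname(avg),
    std_error = unname(adj_se),
    z = unname(z),
    p_value = unname(p),
    stars = p_stars(p)
  )
  models <- tibble::tibble(
    terms = vapply(fits, function(f) {
      if (length(f$terms) == 0) "(intercept only)" else
        paste(sort(f$terms), collapse = " + ")
    }, ""),
    k = vapply(fits, `[[`, 0, "k"),
    AICc = aicc,
    delta = delta,
    weight = NA_real_
  )
  models$weight[in_set] <- w
  models <- dplyr::arrange(models, .data$delta)

  structure(
    list(
      coefficients = coefs, models = models, response = response,
      n = n, n_models = length(fits), n_averaged = sum(in_set),
      delta_max = delta_max
    ),
    class = "averaged_model"
  )
}

build_formula <- function(response, terms) {
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  stats::as.formula(paste(response, "~", rhs), env = baseenv())
}

p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' @method print averaged_model
#' @export
print.averaged_model <- function(x, ...) {
  cat("AICc model averaging for '", x$response, "': ", x$n_averaged,
      " of ", x$n_models, " models with delta AICc < ", x$delta_max,
      " (n = ", x$n, ")\n", sep = "")
  print(x$coefficients, ...)
  invisible(x)
}

#' @method tidy averaged_model
#' @export
tidy.averaged_model <- function(x, ...) x$coefficients

#' @method glance averaged_model
#' @export
glance.averaged_model <- function(x, ...) {
  tibble::tibble(
    response = x$response, n = x$n, n_models = x$n_models,
    n_averaged = x$n_averaged,
    aicc_best = min(x$models$AICc)
  )
}
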