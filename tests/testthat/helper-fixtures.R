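# Shared fixtures and independent oracles used across the suite.

# minimal three-taxon world
tiny_taxa <- function() {
  tibble::tribble(
    ~name, ~habitat, ~body_weight_g, ~status,
    "rat", "forest", 100, NA,
    "mouse", "farmland", 20, NA,
    "plastic", "artificial", NA, NA
  )
}

tiny_cats <- function(n_feral = 3, n_stray = 2) {
  n <- n_feral + n_stray
  tibble::tibble(
    cat_id = sprintf("c%02d", seq_len(n)),
    group = rep(c("feral", "stray"), c(n_feral, n_stray)),
    sex = "female",
    weight_kg = seq(2, 4, length.out = n)
  )
}

# one scat per cat; items = named list cat_id -> tibble(taxon, count)
tiny_scats <- function(cats, items) {
  base <- tibble::tibble(
    scat_id = paste0("s_", cats$cat_id),
    cat_id = cats$cat_id,
    taxon = "rat",
    count = 0L
  )
  extra <- purrr::imap(items, function(df, id) {
    tibble::tibble(scat_id = paste0("s_", id), cat_id = id,
                   taxon = df$taxon, count = as.integer(df$count))
  }) |> purrr::list_rbind()
  dplyr::bind_rows(base[!base$cat_id %in% names(items), ], extra)
}

# two-source zero-uncertainty profile for mixing tests
two_sources <- function(sd = 1e-6, tef_sd = 0) {
  tibble::tibble(
    name = rep(c("alpha", "beta"), each = 2),
    isotope = rep(c("d13C", "d15N"), 2),
    mean = c(-24, 2, -16, 8),
    sd = sd, tef_mean = 0, tef_sd = tef_sd
  )
}

paper_sources <- function() {
  tibble::tibble(
    name = rep(c("forest animals", "farmland animals",
                 "artificial resources"), each = 2),
    isotope = rep(c("d13C", "d15N"), 3),
    mean = c(-24.8, 1.6, -20.9, 6.4, -18.9, 4.6),
    sd = c(2.6, 1.3, 2.1, 1.3, 2.5, 1.2),
    tef_mean = rep(c(2.3, 2.8), 3),
    tef_sd = rep(c(0.3, 0.1), 3)
  )
}

# ---- independent oracles ------------------------------------------------

# two-sided Fisher's exact p by full hypergeometric enumeration
fisher_enum_oracle <- function(x1, n1, x2, n2) {
  m <- x1 + x2
  lo <- max(0, m - n2)
  hi <- min(m, n1)
  probs <- vapply(lo:hi, function(a) {
    exp(lchoose(n1, a) + lchoose(n2, m - a) - lchoose(n1 + n2, m))
  }, 0)
  p_obs <- probs[x1 - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Delaunay edges by brute force: a triple is a triangle iff its open
# circumdisc contains no other point (general-position inputs only)
delaunay_brute_oracle <- function(xy) {
  n <- nrow(xy)
  edges <- matrix(integer(0), ncol = 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- xy[i, ]; b <- xy[j, ]; c <- xy[k, ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) next
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
             (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
             (sum(c^2)) * (b[1] - a[1])) / d
    r2 <- (ux - a[1])^2 + (uy - a[2])^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (xy[others, 1] - ux)^2 + (xy[others, 2] - uy)^2
    if (all(d2 > r2 * (1 - 1e-12))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(edges)
}

edge_key <- function(e) {
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# deterministic balance point of a 3-source, 2-isotope system
solve_mixing_oracle <- function(sources, x_mean) {
  sm <- subsidydiet:::source_matrices(subsidydiet:::check_sources(sources))
  M <- rbind(sm$mean, 1)
  stats::setNames(as.numeric(solve(M, c(x_mean, 1))), sm$names)
}
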