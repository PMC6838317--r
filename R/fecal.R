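#' Daily consumed biomass of a free-living eutherian predator
#'
#' Allometric prediction of the fresh-prey biomass (grams per day) a
#' predator of a given body weight consumes:
#' \deqn{DCB = 3.358 \, W^{0.813} \times 2.86 / 18}
#' where \eqn{W} is the predator body weight in grams, 2.86 corrects for the
#' 65\% water content of prey (100/(100-65)) and 18 is the mean
#' metabolizable energy (kJ) per gram of dry prey.
#'
#' Reported field summaries conventionally truncate DCB to integer grams;
#' this function returns the unrounded value.
#'
#' @param weight_kg Predator body weight(s) in kilograms. Must be positive.
#' @return Numeric vector of daily consumed biomass in grams (fresh prey).
#' @examples
#' dcb(c(1, 3.3, 6))
#' @export
dcb <- function(weight_kg) {
  if (!is.numeric(weight_kg) || length(weight_kg) == 0) {
    abort_invalid("`weight_kg` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    abort_invalid("Predator weights must be finite and positive (kg).")
  }
  w_g <- weight_kg * 1000
  3.358 * w_g^0.813 * 2.86 / 18
}

#' Summarize daily consumed biomass over a set of predators
#'
#' Computes the per-individual DCB first and then summarizes, which differs
#' from evaluating DCB at the mean weight (the allometric exponent < 1 makes
#' DCB concave in weight).
#'
#' @param cats Data frame with a `weight_kg` column (rows with missing
#'   weight are dropped).
#' @return One-row tibble: `n`, `mean_dcb`, `sd_dcb`, `min_dcb`, `max_dcb`
#'   (grams).
#' @examples
#' dcb_summary(tibble::tibble(weight_kg = c(1, 3.3, 6)))
#' @export
dcb_summary <- function(cats) {
  if (!is.data.frame(cats) || !"weight_kg" %in% names(cats)) {
    abort_invalid("`cats` must be a data frame with a `weight_kg` column.")
  }
  w <- cats$weight_kg[!is.na(cats$weight_kg)]
  if (length(w) == 0) {
    abort_invalid("No cats with a recorded weight.")
  }
  d <- dcb(w)
  tibble::tibble(
    n = length(d),
    mean_dcb = mean(d),
    sd_dcb = if (length(d) > 1) stats::sd(d) else 0,
    min_dcb = min(d),
    max_dcb = max(d)
  )
}

resolve_taxa <- function(scats, taxa) {
  unknown <- setdiff(unique(scats$taxon), taxa$name)
  if (length(unknown) > 0) {
    rlang::abort(
      paste0(
        "Scat items reference taxa absent from the taxon table: ",
        paste(unknown, collapse = ", ")
      ),
      class = "subsidydiet_error_resolution"
    )
  }
  invisible(TRUE)
}

# scats joined to cat group; each scat belongs to exactly one cat
scats_with_group <- function(scats, cats) {
  missing_cat <- setdiff(unique(scats$cat_id), cats$cat_id)
  if (length(missing_cat) > 0) {
    abort_invalid(paste0(
      "Scats reference unknown cat_id: ", paste(missing_cat, collapse = ", ")
    ))
  }
  dplyr::left_join(scats, dplyr::select(cats, "cat_id", "group"), by = "cat_id")
}

#' Frequency of occurrence of a prey taxon or habitat category
#'
#' FO is the percentage of scats containing at least one matching item; a
#' scat counts once however many items it holds.
#'
#' @param scats Data frame of scat items: `scat_id`, `cat_id`, `taxon`,
#'   `count` (one row per identified item).
#' @param cats Data frame of predators: `cat_id`, `group`, ...
#' @param taxa Taxon table: `name`, `habitat`, `body_weight_g`.
#' @param selector A taxon name or habitat category (one of
#'   `"forest"`, `"farmland"`, `"unknown"`, `"artificial"`, `"plant"`).
#' @param groups Predator groups to tabulate separately; a `total` row over
#'   those groups is always included.
#' @return Tibble with `group`, `n_scats`, `n_positive`, `fo` (percent).
#' @export
frequency_of_occurrence <- function(scats, cats, taxa, selector,
                                    groups = c("feral", "stray")) {
  resolve_taxa(scats, taxa)
  sel_taxa <- selector_taxa(taxa, selector)
  sg <- scats_with_group(scats, cats)
  sg <- dplyr::filter(sg, .data$group %in% groups)
  per_scat <- sg |>
    dplyr::group_by(.data$scat_id, .data$group) |>
    dplyr::summarise(
      positive = any(.data$taxon %in% sel_taxa & .data$count > 0),
      .groups = "drop"
    )
  by_group <- per_scat |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_scats = dplyr::n(),
      n_positive = sum(.data$positive),
      .groups = "drop"
    )
  total <- tibble::tibble(
    group = "total",
    n_scats = nrow(per_scat),
    n_positive = sum(per_scat$positive)
  )
  dplyr::bind_rows(by_group, total) |>
    dplyr::mutate(fo = 100 * .data$n_positive / .data$n_scats)
}

selector_taxa <- function(taxa, selector) {
  habitats <- c("forest", "farmland", "unknown", "artificial", "plant")
  if (selector %in% habitats) {
    taxa$name[taxa$habitat == selector]
  } else if (selector %in% taxa$name) {
    selector
  } else {
    rlang::abort(
      paste0("Selector '", selector, "' is neither a habitat category nor a known taxon."),
      class = "subsidydiet_error_resolution"
    )
  }
}

#' Contribution of a prey taxon to the predators' daily consumed biomass
#'
#' The statistic used to screen fecal prey for the isotope mixing model,
#' assuming one defecation per day:
#' \deqn{Contribution = 100 \cdot \frac{w \cdot NI / n}{\overline{DCB}}}
#' with \eqn{w} the prey mean body weight (grams), NI the minimum number of
#' prey individuals across all scats, \eqn{n} the number of scats and
#' \eqn{\overline{DCB}} the predators' mean daily consumed biomass. Prey
#' heavier than the heaviest predator's DCB are capped at `max_dcb`: a cat
#' that kills a rabbit does not eat more of it than a day's intake.
#'
#' @param weight_g Prey mean body weight(s), grams.
#' @param ni Minimum number of individuals found over all scats.
#' @param n_scats Total number of scats examined.
#' @param mean_dcb Mean predator DCB, grams.
#' @param max_dcb Cap on effective prey weight, grams (default no cap).
#' @return Contribution(s) in percent, unrounded.
#' @examples
#' contribution_to_dcb(483, 12, 198, 379, 629)
#' @export
contribution_to_dcb <- function(weight_g, ni, n_scats, mean_dcb, max_dcb = Inf) {
  if (any(is.na(weight_g))) {
    rlang::abort(
      "Prey body weight is missing for a taxon with counted individuals.",
      class = "subsidydiet_error_config"
    )
  }
  stopifnot(length(n_scats) == 1, length(mean_dcb) == 1, length(max_dcb) == 1)
  if (n_scats <= 0 || mean_dcb <= 0) {
    abort_invalid("`n_scats` and `mean_dcb` must be positive.")
  }
  if (any(ni < 0)) abort_invalid("`ni` must be non-negative.")
  eff <- pmin(weight_g, max_dcb)
  100 * (eff * ni / n_scats) / mean_dcb
}

#' Per-taxon and per-category diet contribution table
#'
#' Builds the fecal-analysis summary table: frequency of occurrence and
#' prey counts per predator group, and the contribution of each countable
#' taxon (and habitat category) to the mean daily consumed biomass.
#' Taxa without a body weight (insects pooled as unidentified, artificial
#' objects, plants) are tabulated for FO/NI but excluded from contributions.
#'
#' @inheritParams frequency_of_occurrence
#' @param mean_dcb,max_dcb Mean and maximum predator DCB in grams; computed
#'   from `cats` weights when `NULL`.
#' @param groups Predator groups included (their scats define `n`).
#' @return A `contribution_table`: tibble of per-taxon rows (`taxon`,
#'   `habitat`, `body_weight_g`, `fo_total`, `fo_<group>`..., `ni_total`,
#'   `ni_<group>`..., `contribution`) with attributes `categories` (per
#'   habitat subtotals), `n_scats`, `mean_dcb`, `max_dcb`. Contributions are
#'   unrounded; round for display only.
#' @export
contribution_table <- function(scats, cats, taxa,
                               groups = c("feral", "stray"),
                               mean_dcb = NULL, max_dcb = NULL) {
  resolve_taxa(scats, taxa)
  sg <- scats_with_group(scats, cats) |>
    dplyr::filter(.data$group %in% groups)
  if (nrow(sg) == 0) abort_invalid("No scats belong to the requested groups.")
  if (is.null(mean_dcb) || is.null(max_dcb)) {
    ds <- dcb_summary(dplyr::filter(cats, .data$group %in% groups))
    if (is.null(mean_dcb)) mean_dcb <- ds$mean_dcb
    if (is.null(max_dcb)) max_dcb <- ds$max_dcb
  }
  scat_groups <- sg |> dplyr::distinct(.data$scat_id, .data$group)
  n_by_group <- table(scat_groups$group)
  n_scats <- nrow(scat_groups)

  per <- sg |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$taxon, .data$group) |>
    dplyr::summarise(
      n_pos = dplyr::n_distinct(.data$scat_id),
      ni = sum(.data$count),
      .groups = "drop"
    )
  wide <- per |>
    tidyr::pivot_wider(
      names_from = "group",
      values_from = c("n_pos", "ni"),
      values_fill = 0
    )
  for (g in groups) {
    for (pref in c("n_pos_", "ni_")) {
      col <- paste0(pref, g)
      if (!col %in% names(wide)) wide[[col]] <- 0L
    }
  }
  tab <- wide |>
    dplyr::left_join(
      dplyr::select(taxa, taxon = "name", "habitat", "body_weight_g"),
      by = "taxon"
    ) |>
    dplyr::mutate(
      ni_total = rowSums(dplyr::pick(dplyr::all_of(paste0("ni_", groups)))),
      n_pos_total = rowSums(dplyr::pick(dplyr::all_of(paste0("n_pos_", groups)))),
      fo_total = 100 * .data$n_pos_total / n_scats,
      contribution = ifelse(
        is.na(.data$body_weight_g),
        NA_real_,
        100 * (pmin(.data$body_weight_g, max_dcb) * .data$ni_total / n_scats) / mean_dcb
      )
    )
  for (g in groups) {
    tab[[paste0("fo_", g)]] <- 100 * tab[[paste0("n_pos_", g)]] / as.numeric(n_by_group[[g]])
  }
  tab <- tab |>
    dplyr::arrange(
      factor(.data$habitat, levels = c("forest", "farmland", "unknown", "artificial", "plant")),
      dplyr::desc(.data$contribution)
    ) |>
    dplyr::select(
      "taxon", "habitat", "body_weight_g",
      dplyr::starts_with("fo_"), "ni_total", dplyr::starts_with("ni_"),
      "contribution"
    )

  categories <- category_rows(sg, tab, scat_groups, groups, n_scats, n_by_group)
  structure(
    tab,
    class = c("contribution_table", class(tab)),
    categories = categories,
    n_scats = n_scats,
    mean_dcb = mean_dcb,
    max_dcb = max_dcb,
    groups = groups
  )
}

# category subtotals: FO of "any member taxon", NI and contribution as sums
category_rows <- function(sg, tab, scat_groups, groups, n_scats, n_by_group) {
  taxa_map <- dplyr::distinct(tab, .data$taxon, .data$habitat)
  sg_cat <- dplyr::left_join(sg, taxa_map, by = "taxon")
  per_scat <- sg_cat |>
    dplyr::filter(.data$count > 0) |>
    dplyr::distinct(.data$habitat, .data$scat_id, .data$group)
  fo_cat <- per_scat |>
    dplyr::group_by(.data$habitat) |>
    dplyr::summarise(
      fo_total = 100 * dplyr::n_distinct(.data$scat_id) / n_scats,
      .groups = "drop"
    )
  for (g in groups) {
    fg <- per_scat |>
      dplyr::filter(.data$group == g) |>
      dplyr::count(.data$habitat, name = "npos")
    fo_cat[[paste0("fo_", g)]] <- 100 *
      fg$npos[match(fo_cat$habitat, fg$habitat)] / as.numeric(n_by_group[[g]])
    fo_cat[[paste0("fo_", g)]][is.na(fo_cat[[paste0("fo_", g)]])] <- 0
  }
  contrib_cat <- tab |>
    dplyr::group_by(.data$habitat) |>
    dplyr::summarise(
      ni_total = sum(.data$ni_total),
      contribution = if (all(is.na(.data$contribution))) NA_real_
        else sum(.data$contribution, na.rm = TRUE),
      .groups = "drop"
    )
  dplyr::left_join(fo_cat, contrib_cat, by = "habitat")
}

#' Habitat-category subtotals of a contribution table
#'
#' @param x A `contribution_table`.
#' @return Tibble with one row per habitat category: FO per group and
#'   total, summed NI and summed (unrounded) contribution.
#' @export
category_contributions <- function(x) {
  stopifnot(inherits(x, "contribution_table"))
  attr(x, "categories")
}

#' Select important prey taxa as isotope-model sources
#'
#' Prey whose contribution to daily consumed biomass strictly exceeds the
#' threshold are carried forward as candidate sources for the mixing model.
#'
#' @param x A `contribution_table`.
#' @param threshold Contribution cutoff in percent (default 3).
#' @return Tibble of selected taxa with habitat and contribution, ordered
#'   by decreasing contribution.
#' @export
select_sources <- function(x, threshold = 3) {
  stopifnot(inherits(x, "contribution_table"))
  tibble::as_tibble(x) |>
    dplyr::filter(!is.na(.data$contribution), .data$contribution > threshold) |>
    dplyr::arrange(dplyr::desc(.data$contribution)) |>
    dplyr::select("taxon", "habitat", "contribution")
}

#' Compare occurrence of a prey selector between two predator groups
#'
#' Two-sided Fisher's exact test on the 2x2 contain/not-contain table.
#'
#' @inheritParams frequency_of_occurrence
#' @param groups Exactly two predator groups.
#' @return One-row tibble: per-group positives and totals, odds ratio and
#'   `p_value`.
#' @export
fisher_fo_test <- function(scats, cats, taxa, selector,
                           groups = c("feral", "stray")) {
  stopifnot(length(groups) == 2)
  fo <- frequency_of_occurrence(scats, cats, taxa, selector, groups = groups)
  fo <- fo[match(groups, fo$group), ]
  if (any(is.na(fo$n_scats)) || any(fo$n_scats == 0)) {
    abort_invalid("Both groups must contain at least one scat.")
  }
  ft <- stats::fisher.test(matrix(
    c(fo$n_positive[1], fo$n_scats[1] - fo$n_positive[1],
      fo$n_positive[2], fo$n_scats[2] - fo$n_positive[2]),
    nrow = 2, byrow = TRUE
  ))
  tibble::tibble(
    selector = selector,
    group1 = groups[1], positive1 = fo$n_positive[1], n1 = fo$n_scats[1],
    group2 = groups[2], positive2 = fo$n_positive[2], n2 = fo$n_scats[2],
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value
  )
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "subsidydiet_error_invalid_input")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat(
    "Fecal diet contribution table: ", nrow(x), " taxa, ",
    attr(x, "n_scats"), " scats; mean DCB ",
    round(attr(x, "mean_dcb"), 1), " g (cap ",
    round(attr(x, "max_dcb"), 1), " g)\n",
    sep = ""
  )
  print(tibble::as_tibble(x), ...)
  cat("\nCategory subtotals:\n")
  print(attr(x, "categories"), ...)
  invisible(x)
}
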