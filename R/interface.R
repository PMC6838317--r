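# Input validation and the pipeline driver.
#
# CSV dialect everywhere: UTF-8, comma-separated, mandatory header, '.'
# decimal; delta notation spelled d13C / d15N in headers.

table_schemas <- list(
  taxa = list(
    required = c("name", "habitat", "body_weight_g"),
    enums = list(habitat = c("forest", "farmland", "unknown",
                             "artificial", "plant"))
  ),
  scats = list(required = c("scat_id", "cat_id", "taxon", "count")),
  cats = list(
    required = c("cat_id", "group", "sex", "weight_kg"),
    enums = list(
      group = c("feral", "stray", "indoor", "sheltered"),
      sex = c("female", "male", "unknown")
    )
  ),
  consumers = list(required = c("cat_id", "group", "d13C", "d15N")),
  sources = list(required = c("name", "isotope", "mean", "sd",
                              "tef_mean", "tef_sd")),
  shelter = list(required = c("cat_id", "isotope", "days", "delta_diff")),
  landuse = list(required = c("x", "y", "class")),
  buildings = list(required = c("x", "y"))
)

#' Validate pipeline input tables
#'
#' Schema checks (required columns, enum values, types), cross-table
#' reference checks (scat items resolve to taxa, scats resolve to cats)
#' and value plausibility warnings (isotope ratios beyond +/- 60 per mil,
#' non-positive weights). Schema violations are errors; suspicious values
#' are warnings.
#'
#' @param tables Named list of data frames (any subset of `taxa`,
#'   `scats`, `cats`, `consumers`, `sources`, `shelter`, `landuse`,
#'   `buildings`), or a named list of CSV file paths.
#' @return Tibble report: `table`, `row` (NA for table-level), `severity`
#'   (`"error"`/`"warning"`), `message`. Zero rows means fully clean.
#' @export
validate_inputs <- function(tables) {
  if (length(tables) > 0 && all(vapply(tables, is.character, TRUE))) {
    tables <- lapply(tables, function(p) {
      readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    })
  }
  report <- list()
  note <- function(tbl, row, severity, msg) {
    report[[length(report) + 1]] <<- tibble::tibble(
      table = tbl, row = row, severity = severity, message = msg
    )
  }
  for (nm in names(tables)) {
    sch <- table_schemas[[nm]]
    if (is.null(sch)) next
    df <- tables[[nm]]
    missing <- setdiff(sch$required, names(df))
    if (length(missing) > 0) {
      note(nm, NA_integer_, "error",
           paste0("missing column(s): ", paste(missing, collapse = ", ")))
      next
    }
    for (col in names(sch$enums)) {
      bad <- which(!is.na(df[[col]]) & !df[[col]] %in% sch$enums[[col]])
      for (r in bad) {
        note(nm, r, "error",
             paste0("invalid ", col, " value '", df[[col]][r], "'"))
      }
    }
    if (nm == "scats") {
      bad <- which(!is.na(df$count) &
                     (df$count < 0 | df$count != round(df$count)))
      for (r in bad) note(nm, r, "error", "count must be an integer >= 0")
    }
    if (nm == "cats") {
      dup <- which(duplicated(df$cat_id))
      for (r in dup) {
        note(nm, r, "error", paste0("duplicate cat_id '", df$cat_id[r], "'"))
      }
      bad <- which(!is.na(df$weight_kg) & df$weight_kg <= 0)
      for (r in bad) note(nm, r, "error", "weight_kg must be positive")
    }
    if (nm == "consumers") {
      for (col in c("d13C", "d15N")) {
        sus <- which(is.finite(df[[col]]) & abs(df[[col]]) > 60)
        for (r in sus) {
          note(nm, r, "warning",
               paste0(col, " = ", df[[col]][r], " is implausible (>60 permil)"))
        }
        bad <- which(!is.finite(df[[col]]))
        for (r in bad) note(nm, r, "error", paste0(col, " is not finite"))
      }
    }
  }
  if (all(c("scats", "taxa") %in% names(tables))) {
    bad <- which(!tables$scats$taxon %in% tables$taxa$name)
    for (r in bad) {
      note("scats", r, "error",
           paste0("unresolvable taxon '", tables$scats$taxon[r], "'"))
    }
  }
  if (all(c("scats", "cats") %in% names(tables))) {
    bad <- which(!tables$scats$cat_id %in% tables$cats$cat_id)
    for (r in bad) {
      note("scats", r, "error",
           paste0("unknown cat_id '", tables$scats$cat_id[r], "'"))
    }
  }
  if (length(report) == 0) {
    tibble::tibble(table = character(0), row = integer(0),
                   severity = character(0), message = character(0))
  } else {
    purrr::list_rbind(report)
  }
}

#' Run the full diet pipeline
#'
#' Executes, in order: fecal tabulation and source screening, TEF
#' estimation (when a shelter series is supplied, else the shipped
#' defaults), the Bayesian mixing model per group, optional
#' per-individual mixing fits, and the landscape model (factor analysis +
#' MEM + AICc averaging) when spatial layers are supplied. Per-stage
#' tables and a machine-readable JSON summary are written to `out_dir`
#' when given.
#'
#' @param tables Named list of input tibbles: `taxa`, `scats`, `cats`,
#'   `consumers`, `sources` (optional; defaults to the screened-source
#'   profiles), `shelter` (optional), `landuse` + `buildings` (optional —
#'   enables the landscape stage).
#' @param config [mcmc_config()] for the group-level mixing model.
#' @param individual_config [mcmc_config()] for per-individual fits
#'   feeding the landscape stage (shorter chains by default).
#' @param contribution_threshold Source-screening cutoff in percent.
#' @param radius Buffer radius (m) whose covariates feed the factor
#'   analysis.
#' @param stages Character subset of `c("fecal", "tef", "mixing",
#'   "landscape")`.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of stage results (`validation`, `contribution`,
#'   `selected_sources`, `tef`, `posterior`, `landscape`), invisibly
#'   written to disk when `out_dir` is set.
#' @export
run_pipeline <- function(tables,
                         config = mcmc_config(),
                         individual_config = mcmc_config(6000, 1000, 5,
                                                         seed = config$seed),
                         contribution_threshold = 3,
                         radius = 500,
                         stages = c("fecal", "tef", "mixing", "landscape"),
                         out_dir = NULL) {
  report <- validate_inputs(tables)
  if (any(report$severity == "error")) {
    rlang::abort(
      paste0("Input validation failed with ", sum(report$severity == "error"),
             " error(s); see the report."),
      class = "subsidydiet_error_validation",
      report = report
    )
  }
  out <- list(validation = report)

  if ("fecal" %in% stages) {
    ct <- contribution_table(tables$scats, tables$cats, tables$taxa)
    out$contribution <- ct
    out$selected_sources <- select_sources(ct, contribution_threshold)
  }
  if ("tef" %in% stages) {
    out$tef <- if (!is.null(tables$shelter)) {
      fits <- tef_pair(tables$shelter)
      tibble::tibble(
        isotope = names(fits),
        tef_mean = unname(vapply(fits, function(f) f$tef, 0)),
        tef_sd = unname(vapply(fits, function(f) f$tef_se, 0))
      )
    } else {
      default_tefs()
    }
  }
  if ("mixing" %in% stages) {
    sources <- tables$sources %||% default_sources()
    if ("tef" %in% stages) {
      sources <- sources |>
        dplyr::select(-dplyr::any_of(c("tef_mean", "tef_sd"))) |>
        dplyr::left_join(out$tef, by = "isotope")
    }
    consumers <- dplyr::filter(tables$consumers,
                               .data$group %in% c("feral", "stray"))
    out$posterior <- run_mixing_mcmc(consumers, sources, config)

    if ("landscape" %in% stages && !is.null(tables$landuse)) {
      per_cat <- consumers
      per_cat$group_orig <- per_cat$group
      per_cat$group <- per_cat$cat_id
      ind <- run_mixing_mcmc(per_cat, sources, individual_config)
      out$individual_dependence <- ind$summary |>
        dplyr::rename(cat_id = "group")
    }
  }
  if ("landscape" %in% stages && !is.null(tables$landuse) &&
      !is.null(out$individual_dependence)) {
    out$landscape <- landscape_stage(
      tables, out$individual_dependence, radius
    )
  }
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

landscape_stage <- function(tables, dependence, radius) {
  sites <- tables$cats |>
    dplyr::filter(!is.na(.data$x), !is.na(.data$y)) |>
    dplyr::semi_join(dependence, by = "cat_id")
  cov <- buffer_coverage(sites, tables$landuse, tables$buildings,
                         radii = radius)
  cov_cols <- paste0(c("forest_", "residential_", "farmland_",
                       "building_density_"), radius)
  fa <- factor_analysis(cov[cov_cols])
  basis <- mem_construct(sites, duplicates = "jitter")

  deps <- dependence |>
    dplyr::mutate(dep = arcsine_sqrt(.data$mean)) |>
    dplyr::select("cat_id", "source", "dep") |>
    tidyr::pivot_wider(names_from = "source", values_from = "dep")
  dep_cols <- setdiff(names(deps), "cat_id")
  deps <- deps[match(sites$cat_id, deps$cat_id), ]

  sel <- mem_select(basis, deps[dep_cols])
  design <- dplyr::bind_cols(
    deps,
    fa$scores,
    tibble::as_tibble(basis$vectors[, sel$retained, drop = FALSE]),
    sites[c("weight_kg", "sex")]
  )
  fits <- lapply(stats::setNames(dep_cols, dep_cols), function(resp) {
    design$..y <- design[[resp]]
    fit_and_average(
      design, "..y",
      terms = c("Factor1", "Factor2", "weight_kg", "sex", sel$retained)
    )
  })
  list(
    covariates = cov, factors = fa, mem = basis, mem_selection = sel,
    models = fits
  )
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name))
  }
  if (!is.null(out$contribution)) {
    wr(tibble::as_tibble(out$contribution), "contribution_table.csv")
    wr(category_contributions(out$contribution), "category_contributions.csv")
    wr(out$selected_sources, "selected_sources.csv")
  }
  if (!is.null(out$tef)) wr(out$tef, "tef.csv")
  if (!is.null(out$posterior)) {
    wr(out$posterior$summary, "posterior_summary.csv")
    wr(out$posterior$draws, "posterior_draws.csv")
  }
  if (!is.null(out$individual_dependence)) {
    wr(out$individual_dependence, "posterior_by_cat.csv")
  }
  if (!is.null(out$landscape)) {
    wr(out$landscape$covariates, "sites_covariates.csv")
    wr(tidy(out$landscape$factors), "factors.csv")
    wr(tibble::as_tibble(out$landscape$mem$vectors), "mem_scores.csv")
    glm_tab <- purrr::imap(out$landscape$models, function(m, resp) {
      dplyr::mutate(m$coefficients, response = resp, .before = 1)
    }) |> purrr::list_rbind()
    wr(glm_tab, "glm_table.csv")
  }
  summary <- list(
    stages = names(out),
    selected_sources = if (!is.null(out$selected_sources)) {
      out$selected_sources$taxon
    },
    tef = out$tef,
    posterior_summary = if (!is.null(out$posterior)) out$posterior$summary,
    mcmc = if (!is.null(out$posterior)) {
      unclass(out$posterior$config)
    },
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
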