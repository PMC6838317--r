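test_that("allometric DCB matches direct evaluation and rejects bad input", {
  w <- c(1, 2, 3.3, 6)
  expect_equal(dcb(w), 3.358 * (w * 1000)^0.813 * 2.86 / 18)
  expect_equal(dcb(2), 257.5797, tolerance = 1e-6)
  # published range endpoints, truncated to integer grams
  expect_identical(floor(dcb(6)), 629)
  expect_identical(floor(dcb(1)), 146)
  expect_error(dcb(-1), class = "subsidydiet_error_invalid_input")
  expect_error(dcb(numeric(0)), class = "subsidydiet_error_invalid_input")
})

test_that("mean DCB averages per-individual values, not the mean weight", {
  one <- dcb_summary(tibble::tibble(weight_kg = 6))
  expect_equal(one$mean_dcb, dcb(6))
  expect_equal(one$sd_dcb, 0)

  two <- dcb_summary(tibble::tibble(weight_kg = c(1, 6)))
  expect_equal(two$mean_dcb, mean(dcb(c(1, 6))))
  # concave power: mean of DCBs < DCB of mean weight
  expect_lt(two$mean_dcb, dcb(mean(c(1, 6))))
  expect_equal(two$min_dcb, dcb(1))
  expect_equal(two$max_dcb, dcb(6))
  expect_error(dcb_summary(tibble::tibble(weight_kg = NA_real_)),
               class = "subsidydiet_error_invalid_input")
})

test_that("frequency of occurrence counts scats once and resolves selectors", {
  cats <- tiny_cats()
  scats <- tiny_scats(cats, list(
    c01 = tibble::tibble(taxon = c("rat", "rat", "mouse"), count = c(2, 1, 1)),
    c02 = tibble::tibble(taxon = "rat", count = 1),
    c04 = tibble::tibble(taxon = "mouse", count = 3)
  ))
  fo <- frequency_of_occurrence(scats, cats, tiny_taxa(), "rat")
  expect_equal(fo$fo[fo$group == "feral"], 100 * 2 / 3)
  expect_equal(fo$fo[fo$group == "stray"], 0)
  expect_equal(fo$fo[fo$group == "total"], 100 * 2 / 5)
  # category selector equals brute-force scan over raw items
  forest_taxa <- tiny_taxa()$name[tiny_taxa()$habitat == "forest"]
  brute <- scats |>
    dplyr::filter(.data$count > 0, .data$taxon %in% forest_taxa) |>
    dplyr::distinct(.data$scat_id) |>
    nrow()
  fo_cat <- frequency_of_occurrence(scats, cats, tiny_taxa(), "forest")
  expect_equal(fo_cat$n_positive[fo_cat$group == "total"], brute)
  # empty match
  fo0 <- frequency_of_occurrence(scats, cats, tiny_taxa(), "plastic")
  expect_equal(fo0$fo[fo0$group == "total"], 0)
  expect_error(
    frequency_of_occurrence(scats, cats, tiny_taxa(), "unicorn"),
    class = "subsidydiet_error_resolution"
  )
})

test_that("contribution statistic is linear in NI, inverse in n, capped", {
  base <- contribution_to_dcb(483, 12, 198, 379, 629)
  expect_equal(base, 100 * 483 * 12 / 198 / 379)
  expect_equal(contribution_to_dcb(483, 24, 198, 379, 629), 2 * base)
  expect_equal(contribution_to_dcb(483, 12, 99, 379, 629), 2 * base)
  expect_equal(contribution_to_dcb(483, 0, 198, 379, 629), 0)
  # capping never increases, and is a no-op at infinite cap
  expect_lt(contribution_to_dcb(2880, 8, 198, 379, 629),
            contribution_to_dcb(2880, 8, 198, 379, Inf))
  expect_equal(contribution_to_dcb(483, 12, 198, 379, Inf), base)
  expect_error(contribution_to_dcb(NA, 1, 10, 379, 629),
               class = "subsidydiet_error_config")
  expect_error(contribution_to_dcb(100, 1, 0, 379),
               class = "subsidydiet_error_invalid_input")
})

test_that("published worked values reproduce to one decimal", {
  expect_equal(round(contribution_to_dcb(483, 12, 198, 379, 629), 1), 7.7)
  expect_equal(round(contribution_to_dcb(2880, 8, 198, 379, 629), 1), 6.7)
  expect_equal(round(contribution_to_dcb(98, 53, 198, 379, 629), 1), 6.9)
  farmland <- contribution_to_dcb(c(98, 7, 1500), c(53, 15, 2), 198, 379, 629)
  expect_equal(round(sum(farmland), 1), 8.7)
})

test_that("contribution table on the calibrated fixture reproduces the field table", {
  fx <- gen_fecal_table(tokunoshima_scenario(seed = 7), mode = "exact")
  ct <- contribution_table(fx$scats, fx$cats, fx$taxa,
                           mean_dcb = 379, max_dcb = 629)
  tt <- tibble::as_tibble(ct)
  get <- function(taxon) tt$contribution[tt$taxon == taxon]
  expect_equal(round(get("Diplothrix legata"), 1), 7.7)
  expect_equal(round(get("Pentalagus furnessi"), 1), 6.7)
  expect_equal(round(get("Rattus rattus"), 1), 6.9)
  expect_equal(round(get("Tokudaia tokunoshimensis"), 1), 1.3)
  expect_equal(round(get("Gallus gallus domesticus"), 1), 1.7)

  cats_tbl <- category_contributions(ct)
  expect_equal(round(cats_tbl$contribution[cats_tbl$habitat == "farmland"], 1),
               8.7)
  # category subtotal equals the unrounded sum of its members
  expect_equal(
    cats_tbl$contribution[cats_tbl$habitat == "forest"],
    sum(tt$contribution[tt$habitat == "forest"], na.rm = TRUE)
  )
  # the forest subtotal recomputed from per-taxon inputs is ~16.0, not the
  # published 15.5 (documented discrepancy)
  expect_equal(cats_tbl$contribution[cats_tbl$habitat == "forest"],
               15.986, tolerance = 1e-3)
  # uncountable categories carry no contribution
  expect_true(is.na(cats_tbl$contribution[cats_tbl$habitat == "artificial"]))
})

test_that("source selection applies a strict threshold", {
  fx <- gen_fecal_table(tokunoshima_scenario(seed = 7), mode = "exact")
  ct <- contribution_table(fx$scats, fx$cats, fx$taxa,
                           mean_dcb = 379, max_dcb = 629)
  sel <- select_sources(ct, 3)
  expect_setequal(
    sel$taxon,
    c("Diplothrix legata", "Pentalagus furnessi", "Rattus rattus")
  )
  all_pos <- select_sources(ct, 0)
  tt <- tibble::as_tibble(ct)
  expect_equal(nrow(all_pos), sum(tt$contribution > 0, na.rm = TRUE))
  expect_equal(nrow(select_sources(ct, 1e6)), 0)
})

test_that("Fisher's exact test agrees with hypergeometric enumeration", {
  cases <- list(c(35, 174, 0, 24), c(2, 5, 0, 5), c(3, 10, 7, 12),
                c(0, 10, 0, 10))
  for (cs in cases) {
    ours <- stats::fisher.test(matrix(
      c(cs[1], cs[2] - cs[1], cs[3], cs[4] - cs[3]), 2, byrow = TRUE
    ))$p.value
    expect_equal(ours, fisher_enum_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_enum_oracle(0, 10, 0, 10), 1)

  cats <- tiny_cats()
  scats <- tiny_scats(cats, list(
    c01 = tibble::tibble(taxon = "rat", count = 1)
  ))
  res <- fisher_fo_test(scats, cats, tiny_taxa(), "rat")
  expect_equal(res$p_value,
               fisher_enum_oracle(1, 3, 0, 2), tolerance = 1e-9)
  expect_error(
    fisher_fo_test(scats, dplyr::filter(cats, group == "feral"),
                   tiny_taxa(), "rat"),
    class = "subsidydiet_error_invalid_input"
  )
})
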