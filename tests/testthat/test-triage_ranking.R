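test_that("quadrant filter applies inclusive thresholds and preserves order", {
  ref <- rgz_reference()
  records <- tibble::tibble(
    id = c("exact_tie", "better", "worse_aff", "worse_ld"),
    affinity_kcal_mol = c(-8.5, -9.0, -8.4, -9.0),
    ld50_mol_kg = c(2.713, 2.9, 2.9, 2.6)
  )
  kept <- quadrant_filter(records, ref)
  expect_equal(kept$id, c("exact_tie", "better"))

  # the reference row itself is excluded
  with_ref <- dplyr::bind_rows(records,
                               tibble::tibble(id = ref$id,
                                              affinity_kcal_mol = ref$affinity_kcal_mol,
                                              ld50_mol_kg = ref$ld50_mol_kg))
  expect_false(ref$id %in% quadrant_filter(with_ref, ref)$id)

  # missing values name the offending candidate
  records$ld50_mol_kg[2] <- NA
  expect_error(quadrant_filter(records, ref), "better")

  # subset + idempotence
  tab <- read_table3()
  once <- quadrant_filter(tab[!tab$is_reference, ], ref)
  expect_true(all(once$id %in% tab$id))
  expect_equal(quadrant_filter(once, ref), once)
})

test_that("ideal point supports explicit and from-set modes", {
  ip <- ideal_point(affinity_min = -11.1, ld50_max = 2.924)
  expect_equal(ip$affinity_min, -11.1)
  expect_equal(ip$ld50_max, 2.924)
  expect_equal(ip$provenance, "explicit")

  tab <- read_table3()
  cand <- tab[!tab$is_reference, ]
  fs <- ideal_point(cand)
  expect_equal(fs$affinity_min, -9.3)
  expect_equal(fs$ld50_max, 2.924)
  expect_equal(fs$provenance, "from_set")

  one <- cand[1, ]
  single <- ideal_point(one)
  expect_equal(single$affinity_min, one$affinity_kcal_mol)
  expect_equal(single$ld50_max, one$ld50_mol_kg)

  expect_error(ideal_point(cand[0, ]), "non-empty")
})

test_that("Eq-1 distances are computed verbatim on mixed units", {
  ip <- ideal_point(affinity_min = -11.1, ld50_max = 2.924)
  rec <- tibble::tibble(id = "top", affinity_kcal_mol = -9.3, ld50_mol_kg = 2.924)
  r <- euclidean_rank(rec, ip)
  expect_equal(r$distance, 1.8, tolerance = 1e-12)

  at_ideal <- tibble::tibble(id = c("ideal", "other"),
                             affinity_kcal_mol = c(-11.1, -9),
                             ld50_mol_kg = c(2.924, 2.8))
  r2 <- euclidean_rank(at_ideal, ip)
  expect_equal(r2$distance[r2$id == "ideal"], 0)
  expect_equal(r2$ranking[r2$id == "ideal"], 1L)
})

test_that("distance ties break lexicographically by id", {
  ip <- ideal_point(affinity_min = -10, ld50_max = 3)
  recs <- tibble::tibble(id = c("b", "a"),
                         affinity_kcal_mol = c(-9, -9),
                         ld50_mol_kg = c(2.9, 2.9))
  r <- euclidean_rank(recs, ip)
  expect_equal(r$id, c("a", "b"))
})

test_that("ranking is invariant under joint affinity translation", {
  tab <- read_table3()
  cand <- quadrant_filter(tab[!tab$is_reference, ], rgz_reference())
  r0 <- euclidean_rank(cand, ideal_point(affinity_min = -11.1, ld50_max = 2.924))
  shifted <- cand
  shifted$affinity_kcal_mol <- shifted$affinity_kcal_mol + 5
  r1 <- euclidean_rank(shifted, ideal_point(affinity_min = -11.1 + 5, ld50_max = 2.924))
  expect_equal(r1$id, r0$id)
  expect_equal(r1$distance, r0$distance, tolerance = 1e-12)
})

test_that("distance is monotone in each axis holding the other fixed", {
  ip <- ideal_point(affinity_min = -11.1, ld50_max = 2.924)
  aff <- seq(-11.1, -8, by = 0.1)
  d_aff <- euclidean_rank(
    tibble::tibble(id = sprintf("a%02d", seq_along(aff)),
                   affinity_kcal_mol = aff, ld50_mol_kg = 2.8), ip)
  ord <- d_aff$distance[order(d_aff$affinity_kcal_mol)]
  expect_true(all(diff(ord) >= 0))   # moving away from the ideal grows distance
})

test_that("the z-score mode changes only the metric, not the machinery", {
  tab <- read_table3()
  cand <- quadrant_filter(tab[!tab$is_reference, ], rgz_reference())
  rz <- euclidean_rank(cand, ideal_point(affinity_min = -11.1, ld50_max = 2.924),
                       normalize = TRUE)
  expect_equal(sort(rz$ranking), 1:12)
  expect_true(all(diff(rz$distance) >= 0))
})

test_that("BOILED-Egg classification is total and yolk wins overlaps", {
  model <- load_egg_model()
  expect_equal(boiled_egg(10, 300, model), "Out")
  expect_equal(boiled_egg(model$yolk$center_wlogp, model$yolk$center_tpsa, model), "BBB")
  # a point inside the white ellipse but beyond the yolk's TPSA reach
  expect_equal(boiled_egg(2, 120, model), "HIA")
  # the white-ellipse center lies inside the yolk too, and the yolk wins
  expect_equal(boiled_egg(model$white$center_wlogp, model$white$center_tpsa, model), "BBB")

  set.seed(9)
  w <- runif(500, -4, 8); t <- runif(500, 0, 200)
  regions <- boiled_egg(w, t, model)
  expect_true(all(regions %in% c("HIA", "BBB", "Out")))

  # classification constant under tiny perturbations away from boundaries
  for (k in 1:20) {
    eps <- 1e-9
    expect_equal(boiled_egg(w[k] + eps, t[k] - eps, model), regions[k])
  }
})

test_that("run_funnel reproduces the published ranking end to end", {
  tab <- read_table3()
  res <- run_funnel(tab, reference = rgz_reference(),
                    ideal = ideal_point(affinity_min = -11.1, ld50_max = 2.924))
  expect_s3_class(res, "funnel_result")
  expect_equal(res$report$counts$quadrant, 12)
  expect_equal(res$ranked$id[1], "MCULE-9385738471")
  expect_equal(res$ranked$ranking, 1:12)
  expect_equal(res$report$region_source, "annotation")
  expect_true(all(diff(res$ranked$distance) >= 0))

  td <- tidy(res)
  expect_equal(nrow(td), 12)
  gl <- glance(res)
  expect_equal(gl$quadrant, 12)
})

test_that("an empty post-filter set warns and returns an empty result", {
  tab <- read_table3()
  strict_ref <- list(id = "none", affinity_kcal_mol = -99, ld50_mol_kg = 99)
  expect_warning(res <- run_funnel(tab, reference = strict_ref), "no candidates")
  expect_equal(nrow(res$ranked), 0)
})

test_that("funnel stage counts match generator ground truth on 199 synthetic records", {
  ref <- rgz_reference()
  tab <- gen_compound_table(199, 12 / 199, ref, seed = 2024)
  res <- run_funnel(tab, reference = ref,
                    ideal = ideal_point(affinity_min = -11.1, ld50_max = 2.924))
  expect_equal(res$report$counts$input, 199)
  expect_equal(res$report$counts$deduplicated, 199)
  expect_equal(res$report$counts$quadrant, sum(tab$truth_pass))
  expect_setequal(res$ranked$id, tab$id[tab$truth_pass])
})
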