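test_that("descriptors match hand-computable fixtures", {
  dw <- compute_descriptors(water_mol())
  expect_equal(dw$mw, 18.015, tolerance = 1e-3)
  expect_equal(dw$hbd, 1L)
  expect_equal(dw$hba, 1L)

  db <- compute_descriptors(parse_smiles("c1ccccc1"))
  expect_equal(db$hbd, 0L)
  expect_equal(db$hba, 0L)

  rgz <- rgz_mol()
  expect_equal(mol_formula(rgz), "C18H19N3O3S")
  dr <- compute_descriptors(rgz)
  expect_equal(dr$mw, 357.4, tolerance = 0.1)
  expect_true(is.finite(dr$logp) && is.finite(dr$tpsa))
})

test_that("unknown elements error with the element named", {
  bad <- mk_mol("Xx")
  expect_error(compute_descriptors(bad), "Xx")
})

test_that("Lipinski thresholds are inclusive and count violations", {
  at_boundary <- tibble::tibble(mw = 500, hbd = 5L, hba = 10L, logp = 5, tpsa = 50)
  v <- lipinski_violations(at_boundary)
  expect_equal(v$n_violations, 0L)

  over <- tibble::tibble(mw = 501, hbd = 6L, hba = 11L, logp = 6, tpsa = 50)
  expect_equal(lipinski_violations(over)$n_violations, 4L)

  rgz_like <- tibble::tibble(mw = 357.4, hbd = 1L, hba = 4L, logp = 2.0, tpsa = 90)
  expect_equal(lipinski_violations(rgz_like)$n_violations, 0L)
})

test_that("violation count is monotone in each descriptor", {
  base <- tibble::tibble(mw = 300, hbd = 2L, hba = 5L, logp = 3, tpsa = 60)
  n0 <- lipinski_violations(base)$n_violations
  for (col in c("mw", "hbd", "hba", "logp")) {
    worse <- base
    worse[[col]] <- worse[[col]] * 3
    expect_gte(lipinski_violations(worse)$n_violations, n0)
  }
})

test_that("alert catalogs load, validate, and match canonical examples", {
  brenk <- load_alert_catalog("brenk")
  pains <- load_alert_catalog("pains")
  expect_gt(nrow(brenk), 0)
  expect_gt(nrow(pains), 0)
  expect_true(nzchar(attr(brenk, "catalog_version")))

  expect_length(alert_screen(methane_mol(), brenk), 0)

  nitrobenzene <- parse_smiles("O=[N+]([O-])c1ccccc1")
  expect_true(length(alert_screen(nitrobenzene, brenk)) > 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pattern_id\tsmarts\tdescription",
               "ring\tc1ccccc1\tbenzene ring"), path)
  custom <- load_alert_catalog(path)
  expect_equal(alert_screen(parse_smiles("c1ccccc1"), custom), "ring")

  writeLines(c("pattern_id\tsmarts\tdescription", "bad\tc1ccc\tbroken"), path)
  expect_error(load_alert_catalog(path), "SMARTS|malformed")
})

test_that("alert_screen is invariant under atom reordering", {
  brenk <- load_alert_catalog("brenk")
  a <- parse_smiles("O=[N+]([O-])c1ccccc1")
  b <- parse_smiles("c1ccccc1[N+](=O)[O-]")
  expect_equal(sort(alert_screen(a, brenk)), sort(alert_screen(b, brenk)))
})

test_that("qualitative_pass is the conjunction of the three gates", {
  pains <- load_alert_catalog("pains")
  brenk <- load_alert_catalog("brenk")

  clean <- parse_smiles("CCO")
  res <- qualitative_pass(clean, pains, brenk)
  expect_true(res$pass)
  expect_length(res$reasons, 0)

  dirty <- parse_smiles("O=[N+]([O-])c1ccccc1")
  res2 <- qualitative_pass(dirty, pains, brenk)
  expect_false(res2$pass)
  expect_true(any(grepl("^Brenk:", res2$reasons)))

  # conjunction property on assorted molecules
  for (smi in c("CCO", "c1ccccc1", "O=[N+]([O-])c1ccccc1", "CC(=O)Nc1ccc(O)cc1")) {
    mol <- parse_smiles(smi)
    d <- lipinski_violations(compute_descriptors(mol))
    manual <- d$n_violations == 0 &&
      length(alert_screen(mol, pains)) == 0 &&
      length(alert_screen(mol, brenk)) == 0
    expect_equal(qualitative_pass(mol, pains, brenk)$pass, manual)
  }
})

test_that("the ≤1-violation configuration switch loosens only the Lipinski gate", {
  pains <- load_alert_catalog("pains")
  brenk <- load_alert_catalog("brenk")
  # cholesterol-like: logP > 5 (one violation), no alerts
  greasy <- parse_smiles("CCCCCCCCCCCCCCCCCC")
  strict <- qualitative_pass(greasy, pains, brenk)
  loose <- qualitative_pass(greasy, pains, brenk, max_lipinski_violations = 1L)
  expect_false(strict$pass)
  expect_true(loose$pass)
})

test_that("deduplication reproduces the published 274 -> 250 regime", {
  base <- tibble::tibble(
    id = sprintf("HIT-%03d", 1:250),
    affinity_kcal_mol = runif(250, -11, -7),
    ld50_mol_kg = runif(250, 2.3, 3.0)
  )
  dup <- base[sample.int(250, 24), ]
  records <- dplyr::bind_rows(base, dup)[sample.int(274), ]
  out <- deduplicate_hits(records, by = "id")
  expect_equal(nrow(out), 250)
  expect_equal(attr(out, "n_duplicates"), 24L)

  expect_equal(nrow(deduplicate_hits(base, by = "id")), 250)
})

test_that("structure-key deduplication collapses same structure under different ids", {
  records <- tibble::tibble(
    id = c("A", "B", "C"),
    smiles = c("CCO", "OCC", "CCC"),
    affinity_kcal_mol = -8, ld50_mol_kg = 2.8
  )
  out <- deduplicate_hits(records, by = "structure")
  expect_equal(nrow(out), 2)
  expect_equal(out$id, c("A", "C"))
})

test_that("canonical SMILES identify equivalent notations", {
  expect_equal(canonical_smiles("OCC"), canonical_smiles("CCO"))
  expect_false(canonical_smiles("CCO") == canonical_smiles("CCC"))
})
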