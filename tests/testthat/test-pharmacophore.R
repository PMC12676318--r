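test_that("the reference model has the eight published feature kinds", {
  model <- build_reference_model(rgz_mol())
  expect_s3_class(model, "pharmacophore_model")
  expect_equal(nrow(model), 8)
  expect_equal(sum(model$kind == "acceptor"), 1)
  expect_equal(sum(model$kind == "donor"), 1)
  expect_equal(sum(model$kind == "hydrophobic"), 4)
  expect_equal(sum(model$kind == "aromatic"), 2)
})

test_that("ring-centroid features sit on the ring-atom centroid", {
  rgz <- rgz_mol()
  model <- build_reference_model(rgz)
  rings <- aromatic_rings(rgz)
  centroids <- t(vapply(rings, function(r) colMeans(rgz$coords[r, , drop = FALSE]),
                        numeric(3)))
  for (k in which(model$kind == "aromatic")) {
    center <- c(model$x[k], model$y[k], model$z[k])
    d <- sqrt(rowSums(sweep(centroids, 2, center)^2))
    expect_lt(min(d), 0.01)
  }
})

test_that("a conformer without sulfur fails on the hydrophobic sulfur feature", {
  expect_error(build_reference_model(conformer(benzene_mol())), "feature 3|sulfur")
})

test_that("feature perception handles the canonical small cases", {
  benz <- conformer(benzene_mol())
  f <- perceive_features(benz)
  expect_equal(sum(f$kind == "aromatic"), 1)
  cen <- colMeans(benz$coords)
  arom <- f[f$kind == "aromatic", ]
  expect_close(c(arom$x, arom$y, arom$z), cen, tol = 1e-9)

  meoh <- conformer(methanol_mol())
  fm <- perceive_features(meoh)
  expect_equal(sum(fm$kind == "donor"), 1)
  expect_equal(sum(fm$kind == "acceptor"), 1)

  no_coords <- mk_mol(c("C", "O"), rbind(c(1, 2, 1)))
  expect_error(perceive_features(no_coords), "coordinates")
})

test_that("perceived RGZ features cover every reference feature within its radius", {
  rgz <- rgz_mol()
  model <- build_reference_model(rgz, radius = 1.0)
  f <- perceive_features(rgz)
  for (k in seq_len(nrow(model))) {
    same_kind <- f[f$kind == model$kind[k], ]
    d <- sqrt((same_kind$x - model$x[k])^2 + (same_kind$y - model$y[k])^2 +
              (same_kind$z - model$z[k])^2)
    expect_lt(min(d), model$radius[k])
  }
})

test_that("self-match is exact and rigid-motion/atom-relabel invariant", {
  rgz <- rgz_mol()
  model <- build_reference_model(rgz)
  m <- match_pharmacophore(model, rgz, tol = 0.5)
  expect_true(m$matched)
  expect_lt(m$max_deviation, 1e-9)
  expect_false(any(duplicated(m$mapping)))   # injective

  moved <- conformer(rgz, apply_rigid(rgz$coords, rot_z(73), c(5, -1, 2)))
  m2 <- match_pharmacophore(model, moved, tol = 0.5)
  expect_true(m2$matched)
  expect_lt(m2$max_deviation, 1e-6)

  # atom relabeling: reverse atom order
  n <- nrow(rgz$atoms)
  perm <- rev(seq_len(n))
  inv <- order(perm)
  relabeled <- molecule_graph(
    rgz$atoms[perm, ],
    tibble::tibble(i = inv[rgz$bonds$i], j = inv[rgz$bonds$j],
                   order = rgz$bonds$order),
    coords = rgz$coords[perm, ]
  )
  m3 <- match_pharmacophore(model, relabeled, tol = 0.5)
  expect_true(m3$matched)
  expect_equal(m3$max_deviation, m$max_deviation, tolerance = 1e-9)
})

test_that("donor-free decoys never match the model", {
  rgz <- rgz_mol()
  model <- build_reference_model(rgz)
  # decoy without N/O-H: benzene has no donor feature at all
  expect_false(match_pharmacophore(model, conformer(benzene_mol()))$matched)
})

test_that("enlarging the tolerance never unmatches (monotonicity)", {
  rgz <- rgz_mol()
  model <- build_reference_model(rgz)
  # jitter coordinates to make a borderline case
  set.seed(401)
  jit <- conformer(rgz, rgz$coords + matrix(rnorm(3 * nrow(rgz$coords), 0, 0.15),
                                            ncol = 3))
  tols <- c(0.3, 0.6, 1.0, 2.0)
  res <- vapply(tols, function(t) match_pharmacophore(model, jit, tol = t)$matched,
                logical(1))
  expect_true(all(diff(as.integer(res)) >= 0))
  expect_true(res[length(res)])
})

test_that("clique search equals brute-force assignment enumeration on small models", {
  # 3-feature model against a 5-feature perceived set, brute-force oracle
  rgz <- rgz_mol()
  full <- build_reference_model(rgz)
  small <- pharmacophore_model(full[c(1, 2, 3), ], name = "3feat")
  tol <- 0.8
  set.seed(77)
  probe <- conformer(rgz, rgz$coords + matrix(rnorm(3 * nrow(rgz$coords), 0, 0.2),
                                              ncol = 3))
  perceived <- perceive_features(probe)
  dm <- as.matrix(stats::dist(as.matrix(small[, c("x", "y", "z")])))
  dp <- as.matrix(stats::dist(as.matrix(perceived[, c("x", "y", "z")])))
  cands <- lapply(small$kind, function(k) which(perceived$kind == k))
  best <- Inf
  for (a in cands[[1]]) for (b in cands[[2]]) for (cc in cands[[3]]) {
    sel <- c(a, b, cc)
    if (anyDuplicated(sel)) next
    devs <- abs(dm[upper.tri(dm)] - dp[sel, sel][upper.tri(dm)])
    if (all(devs <= tol)) best <- min(best, max(devs))
  }
  got <- match_pharmacophore(small, probe, tol = tol)
  if (is.finite(best)) {
    expect_true(got$matched)
    expect_equal(got$max_deviation, best, tolerance = 1e-9)
  } else {
    expect_false(got$matched)
  }
})

test_that("pharmacophore models round-trip through JSON", {
  model <- build_reference_model(rgz_mol())
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(model, path)
  back <- read_pharmacophore(path)
  expect_equal(back$kind, model$kind)
  expect_equal(back$x, model$x, tolerance = 1e-12)
})
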