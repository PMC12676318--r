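test_that("identical sequences align at 100% identity and coverage", {
  s <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  al <- align_sequences(s, s)
  expect_equal(al$identity, 100)
  expect_equal(al$coverage, 100)
  expect_equal(al$n_mismatches, 0)
})

test_that("planted substitutions give (L-k)/L identity and the exact positions", {
  sp <- gen_sequences(272, 3, seed = 7)
  al <- align_sequences(sp$target, sp$template)
  expect_equal(al$identity, 98.9)
  expect_equal(al$identity, round(100 * 269 / 272, 2))
  expect_equal(al$n_mismatches, 3)
  expect_equal(al$mismatches$target_pos, sp$truth$positions)

  sp0 <- gen_sequences(120, 0, seed = 3)
  expect_equal(align_sequences(sp0$target, sp0$template)$identity, 100)
})

test_that("a truncated template yields partial coverage with free end gaps", {
  sp <- gen_sequences(272, 3, window = c(30, 170), seed = 8)
  al <- align_sequences(sp$target, sp$template)
  expect_equal(al$coverage, sp$truth$coverage)
  expect_equal(al$identity, sp$truth$identity)
  expect_lt(al$coverage, 100)
})

test_that("identity and mismatch listing are symmetric; coverage is not", {
  sp <- gen_sequences(200, 4, window = c(20, 150), seed = 12)
  fwd <- align_sequences(sp$target, sp$template)
  rev_ <- align_sequences(sp$template, sp$target)
  expect_equal(fwd$identity, rev_$identity)
  expect_equal(fwd$n_mismatches, rev_$n_mismatches)
  expect_equal(sort(paste(fwd$mismatches$target_res, fwd$mismatches$template_res)),
               sort(paste(rev_$mismatches$template_res, rev_$mismatches$target_res)))
  expect_false(isTRUE(all.equal(fwd$coverage, rev_$coverage)))

  expect_error(align_sequences("", "ACD"), "non-empty")
})

test_that("dihedral angles agree with an independent vector-algebra oracle", {
  oracle_dihedral <- function(p1, p2, p3, p4) {
    # projection-based formulation, independent of the atan2 route
    b2 <- p3 - p2
    u <- (p1 - p2) - sum((p1 - p2) * b2) / sum(b2^2) * b2
    v <- (p4 - p3) - sum((p4 - p3) * b2) / sum(b2^2) * b2
    ang <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    s <- sign(sum(pracma::cross(u, v) * b2))
    if (s < 0) -ang else ang
  }
  set.seed(61)
  for (k in 1:25) {
    pts <- matrix(rnorm(12, sd = 2), ncol = 3)
    got <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    delta <- abs(got - want) %% 360
    expect_lt(min(delta, 360 - delta), 1e-9)
  }
})

test_that("an ideal helix round-trips its phi/psi angles", {
  bb <- build_backbone(12, phi = -57, psi = -47)
  angles <- phi_psi(bb)
  inner <- angles[!is.na(angles$phi) & !is.na(angles$psi), ]
  expect_gt(nrow(inner), 5)
  expect_true(all(abs(inner$phi - (-57)) < 5))
  expect_true(all(abs(inner$psi - (-47)) < 5))

  # termini carry one NA each
  expect_true(is.na(angles$phi[1]))
  expect_true(is.na(angles$psi[nrow(angles)]))
})

test_that("a 2-residue peptide has psi-only then phi-only", {
  bb <- build_backbone(2)
  a <- phi_psi(bb)
  expect_true(is.na(a$phi[1]) && !is.na(a$psi[1]))
  expect_true(!is.na(a$phi[2]) && is.na(a$psi[2]))
})

test_that("dihedrals are rigid-motion invariant and chain breaks cut chaining", {
  bb <- build_backbone(8)
  a0 <- phi_psi(bb)
  co <- apply_rigid(as.matrix(bb[, c("x", "y", "z")]), rot_z(118), c(10, -3, 6))
  bb2 <- bb
  bb2$x <- co[, 1]; bb2$y <- co[, 2]; bb2$z <- co[, 3]
  a1 <- phi_psi(bb2)
  expect_equal(a1$phi, a0$phi, tolerance = 1e-9)
  expect_equal(a1$psi, a0$psi, tolerance = 1e-9)

  # shift the last 3 residues far away: CA-CA > 4.5 A breaks the chain
  broken <- bb
  far <- broken$resid >= 6
  broken$x[far] <- broken$x[far] + 100
  ab <- phi_psi(broken)
  expect_true(is.na(ab$psi[ab$resid == 5]))
  expect_true(is.na(ab$phi[ab$resid == 6]))
})

test_that("residues missing backbone atoms are skipped with a message", {
  bb <- build_backbone(5)
  bb <- bb[!(bb$resid == 3 & bb$name == "CA"), ]
  expect_message(a <- phi_psi(bb), "skipping")
  expect_false(3 %in% a$resid)
})

test_that("Ramachandran classification is total with the stated edge rule", {
  rmap <- load_rama_map()
  helix <- phi_psi(build_backbone(20, phi = -57, psi = -47))
  res <- rama_classify(helix, rmap)
  done <- res$labels[!is.na(res$labels$label), ]
  expect_true(all(done$label == "favored"))
  expect_equal(unname(res$percent["favored"]), 100)

  empty <- rama_classify(helix[0, ], rmap)
  expect_equal(sum(empty$counts), 0)

  # a point on the favored polygon edge takes the favorable class
  # (the bundled alpha region spans phi in [-120, -30], psi in [-80, -5])
  on_edge <- tibble::tibble(resid = 1L, resname = "ALA",
                            phi = -120, psi = -40)
  expect_equal(rama_classify(on_edge, rmap)$labels$label, "favored")

  # far-off point is an outlier
  off <- tibble::tibble(resid = 1L, resname = "ALA", phi = 120, psi = -120)
  expect_equal(rama_classify(off, rmap)$labels$label, "outlier")

  gl <- glance(res)
  expect_equal(gl$pct_favored, 100)
})
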