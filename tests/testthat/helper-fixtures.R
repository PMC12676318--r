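# Code-built fixtures shared across test files. Everything here is plain
# text / constructed in code so the suite runs fully offline.

fix_path <- function(...) {
  system.file("extdata", ..., package = "hitfunnel")
}

table3_path <- function() fix_path("table3_hits.csv")
rgz_sdf_path <- function() fix_path("rgz_synthetic.sdf")

read_table3 <- function() {
  read_compound_table(table3_path(), reference_ids = "MCULE-8293284864")
}

rgz_reference <- function() {
  list(id = "MCULE-8293284864", affinity_kcal_mol = -8.5, ld50_mol_kg = 2.713)
}

rgz_mol <- function() {
  read_structures(rgz_sdf_path(), format = "sdf")[[1]]
}

# ---- small molecules built in code ----

mk_mol <- function(elements, bonds = NULL, coords = NULL, charges = 0L,
                   name = NULL) {
  n <- length(elements)
  atoms <- tibble::tibble(element = elements,
                          charge = rep_len(as.integer(charges), n))
  if (is.null(bonds)) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = numeric())
  } else {
    bonds <- tibble::tibble(i = as.integer(bonds[, 1]),
                            j = as.integer(bonds[, 2]),
                            order = as.numeric(bonds[, 3]))
  }
  molecule_graph(atoms, bonds, coords = coords, name = name)
}

water_mol <- function() {
  mk_mol(c("O", "H", "H"), rbind(c(1, 2, 1), c(1, 3, 1)), name = "water")
}

methane_mol <- function() mk_mol("C", name = "methane")

ethane_mol <- function() mk_mol(c("C", "C"), rbind(c(1, 2, 1)), name = "ethane")

# linear heavy-atom chain with distinct elements: only the identity
# automorphism survives
cno_mol <- function() {
  mk_mol(c("C", "N", "O"), rbind(c(1, 2, 1), c(2, 3, 1)),
         coords = cbind(0:2, 0, 0), name = "cno")
}

methanol_mol <- function() {
  mk_mol(c("C", "O"), rbind(c(1, 2, 1)),
         coords = rbind(c(0, 0, 0), c(1.4, 0, 0)), name = "methanol")
}

# flat hexagonal benzene with uniform aromatic (order 4) ring bonds
benzene_mol <- function() {
  ang <- (0:5) * pi / 3
  mk_mol(rep("C", 6),
         cbind(1:6, c(2:6, 1), 4),
         coords = cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
         name = "benzene")
}

# ---- rigid motions ----

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

apply_rigid <- function(coords, R = diag(3), t = c(0, 0, 0)) {
  sweep(coords %*% t(R), 2, t, "+")
}

# ---- ideal polypeptide backbone via NeRF internal-coordinate placement ----

place_atom <- function(a, b, c_, r, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180
  chi <- chi_deg * pi / 180
  bc <- (c_ - b) / sqrt(sum((c_ - b)^2))
  n <- pracma::cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma::cross(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi), r * sin(theta) * sin(chi))
  c_ + d[1] * bc + d[2] * m + d[3] * n
}

# backbone (N, CA, C per residue) built from exact phi/psi targets
build_backbone <- function(n_res, phi = -57, psi = -47, omega = 180) {
  atoms <- list(
    c(0, 0, 0),                 # N1
    c(1.458, 0, 0),             # CA1
    c(1.458 + 1.525 * cos((180 - 111.2) * pi / 180),
      1.525 * sin((180 - 111.2) * pi / 180), 0)  # C1
  )
  for (i in seq_len(n_res - 1)) {
    k <- length(atoms)
    N <- place_atom(atoms[[k - 2]], atoms[[k - 1]], atoms[[k]], 1.329, 116.2, psi)
    CA <- place_atom(atoms[[k - 1]], atoms[[k]], N, 1.458, 121.7, omega)
    C <- place_atom(atoms[[k]], N, CA, 1.525, 111.2, phi)
    atoms <- c(atoms, list(N, CA, C))
  }
  co <- do.call(rbind, atoms)
  tibble::tibble(
    name = rep(c("N", "CA", "C"), n_res),
    resid = rep(seq_len(n_res), each = 3),
    resname = "ALA",
    x = co[, 1], y = co[, 2], z = co[, 3]
  )
}

# ---- trajectories ----

mk_traj <- function(frames, names = NULL, resids = NULL) {
  n <- nrow(frames[[1]])
  trajectory(frames, tibble::tibble(
    name = names %||% rep("CA", n),
    resid = resids %||% seq_len(n),
    resname = rep("ALA", n),
    element = rep("C", n)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

expect_close <- function(actual, expected, tol = 1e-9) {
  expect_true(all(abs(actual - expected) <= tol),
              label = paste0("max|diff| = ", max(abs(actual - expected))))
}
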