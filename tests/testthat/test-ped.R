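water_mol <- function() {
  molecule(c("O", "H", "H"),
           rbind(c(0, 0, 0),
                 c(0.9572, 0, 0),
                 c(-0.2399872, 0.9266272, 0)))
}

test_that("automatic internal coordinates enumerate water and acetamide correctly", {
  ic_w <- auto_internal_coords(water_mol())
  expect_equal(sum(ic_w$kind == "bond"), 2L)
  expect_equal(sum(ic_w$kind == "angle"), 1L)
  expect_equal(sum(ic_w$kind == "torsion"), 0L)

  a <- amide_surrogate()
  ic_a <- auto_internal_coords(a$mol)
  expect_equal(sum(ic_a$kind == "bond"), 8L)   # hand count: C=O, C-N, C-C, 2 N-H, 3 C-H

  # threshold stability: a 1e-9 relative dilation changes nothing
  mol2 <- molecule(a$mol$elements, a$mol$coordinates * (1 + 1e-9))
  ic_b <- auto_internal_coords(mol2)
  expect_identical(ic_a$label, ic_b$label)

  expect_warning(auto_internal_coords(
    molecule(c("O", "H", "H", "O"),
             rbind(water_mol()$coordinates, c(10, 10, 10)))),
    "disconnected")
})

test_that("B-matrix rows: unit bond derivative and finite-difference agreement", {
  dia <- molecule(c("C", "O"), rbind(c(0, 0, 0), c(0, 0, 1.2)))
  ic <- auto_internal_coords(dia)
  B <- b_matrix(dia, ic)
  expect_equal(B[1, ], c(0, 0, -1, 0, 0, 1))

  a <- amide_surrogate()
  ic_a <- auto_internal_coords(a$mol)
  B_a <- b_matrix(a$mol, ic_a)
  # central finite differences, h = 1e-5 Angstrom
  h <- 1e-5
  xyz <- a$mol$coordinates
  value_of <- function(row, coords) {
    idx <- unlist(ic_a[row, c("i", "j", "k", "l")]); idx <- idx[!is.na(idx)]
    isovib:::.int_coord_grad(ic_a$kind[row], idx, coords)$value
  }
  wrap <- function(x) atan2(sin(x), cos(x))  # torsions live on the circle
  for (row in seq_len(nrow(ic_a))) {
    num <- numeric(3 * nrow(xyz))
    for (c3 in seq_len(3 * nrow(xyz))) {
      at <- (c3 - 1) %/% 3 + 1; ax <- (c3 - 1) %% 3 + 1
      xp <- xyz; xp[at, ax] <- xp[at, ax] + h
      xm <- xyz; xm[at, ax] <- xm[at, ax] - h
      dv <- value_of(row, xp) - value_of(row, xm)
      if (ic_a$kind[row] == "torsion") dv <- wrap(dv)
      num[c3] <- dv / (2 * h)
    }
    expect_lt(max(abs(B_a[row, ] - num)), 1e-6)
  }
})

test_that("B matrix is invariant under rigid translation", {
  a <- imidate_surrogate("pcm")
  ic <- auto_internal_coords(a$mol)
  B1 <- b_matrix(a$mol, ic)
  shifted <- molecule(a$mol$elements,
                      sweep(a$mol$coordinates, 2, c(1.3, -2.1, 0.7), `+`))
  B2 <- b_matrix(shifted, ic)
  expect_lt(max(abs(B1 - B2)), 1e-10)
})

test_that("PED: diatomic stretch is 100%; uncoupled oscillators stay block-diagonal", {
  co <- toy_co_oscillator(1700)
  nm <- normal_modes(co$mol, co$hessian)
  pt <- ped(nm, co$hessian, co$mol, co$coords)
  expect_equal(nrow(pt$ped), 1L)
  expect_equal(unname(pt$ped[1, 1]), 1)

  # two independent diatomics in one system, no inter-fragment coupling
  ff <- toy_force_field(
    elements = c("C", "O", "C", "N"),
    coordinates = rbind(c(0, 0, 0), c(1.23, 0, 0),
                        c(0, 6, 0), c(1.20, 6, 0)),
    bonds = data.frame(i = c(1, 3), j = c(2, 4), k = c(11, 10),
                       q = c(0.5, 0.5)))
  tm <- toy_molecule(ff)
  nm2 <- normal_modes(tm$mol, tm$hessian)
  pt2 <- ped(nm2, tm$hessian, tm$mol, tm$coords)
  expect_equal(nrow(pt2$ped), 2L)
  for (r in 1:2) {
    expect_equal(max(pt2$ped[r, ]), 1, tolerance = 1e-10)
    expect_equal(min(pt2$ped[r, ]), 0, tolerance = 1e-10)
  }
})

test_that("PED rows are normalized and invariant under rigid rotation", {
  m <- amide_surrogate()
  nm <- normal_modes(m$mol, m$hessian)
  pt <- ped(nm, m$hessian, m$mol, m$coords)
  expect_true(all(abs(rowSums(pt$ped) - 1) < 0.02))

  # rotate geometry and Hessian consistently
  th <- 0.7; R <- rbind(c(cos(th), -sin(th), 0),
                        c(sin(th), cos(th), 0),
                        c(0, 0, 1))
  xyz_r <- m$mol$coordinates %*% t(R)
  Rbig <- kronecker(diag(9), R)
  H_r <- Rbig %*% m$hessian %*% t(Rbig)
  H_r <- (H_r + t(H_r)) / 2
  mol_r <- molecule(m$mol$elements, xyz_r)
  nm_r <- normal_modes(mol_r, H_r)
  pt_r <- ped(nm_r, H_r, mol_r, m$coords)
  ped_sorted <- function(p) p$ped[order(-p$summary$frequency), ]
  expect_lt(max(abs(ped_sorted(pt) - ped_sorted(pt_r))), 1e-6)
})

test_that("rank-deficient coordinate sets are rejected with guidance", {
  m <- amide_surrogate()
  nm <- normal_modes(m$mol, m$hessian)
  bonds_only <- m$coords[m$coords$kind == "bond", ]
  expect_error(ped(nm, m$hessian, m$mol, bonds_only), "rank")
})

test_that("band assignment combines PED dominance with shift thresholds", {
  m <- amide_surrogate()
  nm <- normal_modes(m$mol, m$hessian, scale = 0.965)
  nm15 <- normal_modes(m$mol, m$hessian, iso = isotope_pattern(N3 = "15N"),
                       scale = 0.965)
  pr <- suppressWarnings(pair_modes(nm, nm15))
  pt <- ped(nm, m$hessian, m$mol, m$coords)
  asg <- assign_band(pt, pr)
  co_mode <- pt$summary$mode[which.max(pt$ped[, "r(C1-O2)"])]
  expect_equal(asg$label[asg$mode == co_mode], "C=O")

  i <- imidate_surrogate("pcm")
  nmi <- normal_modes(i$mol, i$hessian, scale = 0.965)
  nmi15 <- normal_modes(i$mol, i$hessian, iso = isotope_pattern(N3 = "15N"),
                        scale = 0.965)
  pri <- suppressWarnings(pair_modes(nmi, nmi15))
  pti <- ped(nmi, i$hessian, i$mol, i$coords)
  asgi <- assign_band(pti, pri)
  cn_mode <- pti$summary$mode[which.max(pti$ped[, "r(C1-N3)"])]
  expect_equal(asgi$label[asgi$mode == cn_mode], "C=N")

  # an intermediate shift is never silently classified
  fake_ped <- pt
  fake_shift <- pr
  fake_shift$shift[fake_shift$mode_a == co_mode] <- 6
  asg2 <- assign_band(fake_ped, fake_shift)
  expect_equal(asg2$label[asg2$mode == co_mode], "ambiguous")
})
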