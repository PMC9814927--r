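# Hydrogen-bond motif classification: distance/angle rule and the
# molecule-level graph under periodicity.

acid_molecule <- function() {
  rigid_molecule(c("C", "O", "O", "H"),
                 rbind(c(0, 0, 0), c(0.6, 1.0, 0), c(0.6, -1.0, 0),
                       c(1.55, -1.0, 0)),
                 name = "acid")
}
acid_donors <- data.frame(mol = "acid", d = 3, h = 4)
acid_acceptors <- data.frame(mol = "acid", a = 2)

dimer_structure <- function(cell = lattice(14, 14, 10)) {
  mol <- acid_molecule()
  A <- cell_matrix(cell)
  masses <- c(12.011, 15.999, 15.999, 1.008)
  loc <- rbind(c(0, 0, 0), c(0.6, 1.0, 0), c(0.6, -1.0, 0), c(1.55, -1.0, 0))
  com <- colSums(loc * masses) / sum(masses)
  fA <- as.numeric(solve(A) %*% (com + c(3, 3, 3)))
  fB <- as.numeric(solve(A) %*% (c(2 * 1.925, 0, 0) - com + c(3, 3, 3)))
  crystal_structure(cell, list(acid = mol),
                    list(placement("acid", fA),
                         placement("acid", fB, inv = -1)))
}

test_that("a reciprocal doubly-bonded pair classifies as dimer", {
  r <- classify_hbond_motif(dimer_structure(), acid_donors, acid_acceptors)
  expect_equal(r$motif, "dimer")
  expect_equal(nrow(r$bonds), 2)
  expect_equal(r$components$size, 2)
  expect_equal(r$components$bonds, 2)
  expect_false(r$components$periodic)
})

test_that("a 1-D periodic bond sequence classifies as chain", {
  mol <- acid_molecule()
  s <- crystal_structure(lattice(2.65, 12, 10), list(acid = mol),
                         list(placement("acid", c(0, 0.25, 0.25))))
  r <- classify_hbond_motif(s, acid_donors, acid_acceptors)
  expect_equal(r$motif, "chain")
  expect_true(r$components$periodic)
})

test_that("the distance threshold vdW-sum + 0.1 is a strict inequality", {
  # collinear O-H...O with the H...O separation set exactly
  mol <- rigid_molecule(c("O", "H"), rbind(c(0, 0, 0), c(0.95, 0, 0)),
                        name = "oh")
  don <- data.frame(mol = "oh", d = 1, h = 2)
  acc <- data.frame(mol = "oh", a = 1)
  mk <- function(target) {
    # centre separation D gives H...O(next) = D - 0.95 along x
    a <- 20
    crystal_structure(lattice(a, a, a), list(oh = mol),
                      list(placement("oh", c(0, 0, 0)),
                           placement("oh", c((target + 0.95) / a, 0, 0))))
  }
  r_in <- classify_hbond_motif(mk(2.82 - 1e-6), don, acc) # just below threshold
  expect_gt(nrow(r_in$bonds), 0)
  expect_equal(min(r_in$bonds$dist), 2.82, tolerance = 1e-4)
  # at/above the threshold (within float resolution): not a bond
  r_at <- classify_hbond_motif(mk(2.82 + 1e-6), don, acc)
  expect_equal(nrow(r_at$bonds), 0)
})

test_that("the 125-degree angle threshold is a strict inequality", {
  # donor geometry built so the D-H...A angle is exactly controlled
  mk_angle <- function(theta_deg) {
    th <- theta_deg * pi / 180
    don_mol <- rigid_molecule(c("O", "H"),
                              rbind(0.95 * c(cos(th), sin(th), 0), c(0, 0, 0)),
                              name = "don")
    acc_mol <- rigid_molecule("O", matrix(0, 1, 3), name = "acc")
    a <- 20
    A <- cell_matrix(lattice(a, a, a))
    pH <- c(5, 5, 5)
    centre1 <- pH - don_mol$local[2, ] # place so H sits at pH
    pA <- pH + c(2.0, 0, 0)
    crystal_structure(lattice(a, a, a), list(don = don_mol, acc = acc_mol),
                      list(placement("don", as.numeric(solve(A) %*% centre1)),
                           placement("acc", as.numeric(solve(A) %*% pA))))
  }
  don <- data.frame(mol = "don", d = 1, h = 2)
  acc <- data.frame(mol = "acc", a = 1)
  r_open <- classify_hbond_motif(mk_angle(127), don, acc)
  expect_gt(nrow(r_open$bonds), 0)
  expect_equal(min(r_open$bonds$angle), 127, tolerance = 1e-5)
  # at/just below the threshold (within float resolution): no bond
  r_shut <- classify_hbond_motif(mk_angle(125 - 1e-4), don, acc)
  expect_equal(nrow(r_shut$bonds), 0)
})

test_that("motif classification is invariant under supercell expansion", {
  s <- dimer_structure()
  r1 <- classify_hbond_motif(s, acid_donors, acid_acceptors)
  ssup <- transform_cell(s, diag(c(1, 2, 1)))
  r2 <- classify_hbond_motif(ssup, acid_donors, acid_acceptors)
  expect_equal(r1$motif, r2$motif)
  expect_equal(nrow(r2$bonds), 2 * nrow(r1$bonds))
})

test_that("fixture profiles carry the engineered motif labels", {
  dc <- fx_dimer_chain()
  expect_equal(dc$motifs, c("dimer", "chain"))
  ls <- fx_layer()
  expect_equal(length(unique(ls$motifs)), 1) # same label for both minima
})

test_that("missing donor/acceptor declarations raise a configuration error", {
  s <- dimer_structure()
  expect_error(classify_hbond_motif(s, NULL, acid_acceptors), "required")
  expect_error(classify_hbond_motif(s, acid_donors[0, ], acid_acceptors),
               "required")
})
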