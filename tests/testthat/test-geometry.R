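test_that("signed dihedral matches symmetry-forced values and errors on degenerate input", {
  # planar cis -> 0, planar trans -> 180
  expect_equal(compute_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(compute_dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_error(compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(compute_dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "central bond")
})

test_that("dihedral agrees with the cross-product oracle and with bio3d on random fixtures", {
  set.seed(101)
  for (i in 1:100) {
    p <- replicate(4, rnorm(3, sd = 2), simplify = FALSE)
    skip_geom <- tryCatch({ oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]); FALSE },
                          error = function(e) TRUE)
    if (skip_geom) next
    d <- compute_dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    expect_equal(d, oracle_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-9)
    expect_equal(d, bio3d::torsion.xyz(unlist(p), atm.inc = 4),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("dihedral is invariant under rigid transforms and path reversal", {
  set.seed(102)
  for (i in 1:25) {
    p <- replicate(4, rnorm(3, sd = 2), simplify = FALSE)
    d0 <- tryCatch(compute_dihedral(p[[1]], p[[2]], p[[3]], p[[4]]),
                   error = function(e) NULL)
    if (is.null(d0)) next
    tf <- random_rigid_transform()
    q <- lapply(p, tf)
    expect_equal(compute_dihedral(q[[1]], q[[2]], q[[3]], q[[4]]), d0,
                 tolerance = 1e-9)
    expect_equal(compute_dihedral(p[[4]], p[[3]], p[[2]], p[[1]]), d0,
                 tolerance = 1e-9)
  }
})

test_that("chromophore dihedrals round-trip constructed angles and wrap Delta", {
  d <- chromophore_dihedrals(make_dihedral_frame(30, 10))
  expect_equal(d$phi_deg, 30, tolerance = 1e-9)
  expect_equal(d$tau_deg, 10, tolerance = 1e-9)
  expect_equal(d$delta_deg, 20, tolerance = 1e-9)
  # wrapping of Delta across the branch cut
  d2 <- chromophore_dihedrals(make_dihedral_frame(170, -150))
  expect_equal(d2$delta_deg, wrap_angle(170 - (-150)), tolerance = 1e-9)
  expect_equal(d2$delta_deg, -40, tolerance = 1e-9)
  # missing atom -> named hard error
  tr <- make_dihedral_frame(10, 5)
  tr$atoms$name[1] <- "XX"
  expect_error(chromophore_dihedrals(tr), "CD")
})

test_that("angle wrapping maps to (-180, 180] with -180 -> 180", {
  expect_equal(wrap_angle(c(190, -190, 360, -180, 180, 0)),
               c(-170, 170, 0, 180, 180, 0))
})

test_that("hydrogen-bond detection honours distance, angle and region cutoffs", {
  # constructed O-H...O at d = 3.0 A, 10 deg deviation: one bond
  g1 <- gen_hbond_frames(k = 1, n_decoys = 0, jitter_A = 0, seed = 1)
  hb <- detect_hbonds(g1$frame, chromophore = g1$chromophore)
  expect_equal(nrow(hb), 1L)
  expect_true(hb$dist_DA <= 3.2 && hb$deviation_deg <= 20)
  # same geometry at d = 3.3 A: excluded
  g0 <- gen_hbond_frames(k = 0, n_decoys = 1, jitter_A = 0, seed = 1)
  expect_equal(nrow(detect_hbonds(g0$frame, chromophore = g0$chromophore)), 0L)
  # planted k bonds among decoys, k in 0..5, including the boundary decoy
  for (k in 0:5) {
    g <- gen_hbond_frames(k = k, n_decoys = 3, boundary_decoy = TRUE, seed = k + 10)
    found <- detect_hbonds(g$frame, chromophore = g$chromophore)
    expect_equal(nrow(found), k)
    if (k > 0) expect_setequal(found$donor, g$truth$donor)
  }
  expect_error(detect_hbonds(g1$frame, chromophore = integer(0)), "chromophore")
})

test_that("boundary semantics: donor-acceptor distance exactly at cutoff counts, 3.21 does not", {
  g <- gen_hbond_frames(k = 1, n_decoys = 0, jitter_A = 0)
  # move the acceptor to exactly 3.2 A
  g$frame[g$truth$acceptor, c("x", "y", "z")] <-
    g$frame[g$truth$donor, c("x", "y", "z")] + c(0, 0, 3.2)
  expect_equal(nrow(detect_hbonds(g$frame, chromophore = g$chromophore)), 1L)
  g$frame[g$truth$acceptor, "z"] <- g$frame[g$truth$donor, "z"] + 3.21
  expect_equal(nrow(detect_hbonds(g$frame, chromophore = g$chromophore)), 0L)
})

test_that("hydrogen-bond count is invariant under rigid transforms and atom reordering", {
  g <- gen_hbond_frames(k = 3, n_decoys = 2, seed = 42)
  n0 <- nrow(detect_hbonds(g$frame, chromophore = g$chromophore))
  set.seed(7)
  tf <- random_rigid_transform()
  fr <- g$frame
  xyz <- t(apply(as.matrix(fr[, c("x", "y", "z")]), 1, tf))
  fr[, c("x", "y", "z")] <- xyz
  expect_equal(nrow(detect_hbonds(fr, chromophore = g$chromophore)), n0)
  perm <- sample(nrow(fr))
  fr2 <- fr[perm, ]
  chrom2 <- match(g$chromophore, perm)
  expect_equal(nrow(detect_hbonds(fr2, chromophore = chrom2)), n0)
})

test_that("chromophore-only census mode excludes environment-environment bonds", {
  g <- gen_hbond_frames(k = 2, n_decoys = 0, seed = 3)
  # planted bonds are between environment atoms near the chromophore:
  # counted in shell mode, absent in chromophore mode
  expect_equal(nrow(detect_hbonds(g$frame, g$chromophore, mode = "shell")), 2L)
  expect_equal(nrow(detect_hbonds(g$frame, g$chromophore, mode = "chromophore")), 0L)
})

test_that("planarity statistics use the population estimator and pool exactly", {
  expect_error(planarity_stats(numeric(0)), "empty")
  s <- planarity_stats(rep(7.40, 50))
  expect_equal(s$mean_delta, 7.40)
  expect_equal(s$std_delta, 0)
  # Monte-Carlo: Gaussian Delta with sigma 16.7, n = 2000
  set.seed(11)
  x <- rnorm(2000, 7.4, 16.7)
  s2 <- planarity_stats(x)
  expect_lt(abs(s2$std_delta - 16.7) / 16.7, 0.05)
  # pooled-moment combination over a concatenation
  a <- rnorm(400, 5, 10); b <- rnorm(700, -2, 4)
  sa <- planarity_stats(a); sb <- planarity_stats(b)
  sc <- planarity_stats(c(a, b))
  n <- sa$n_frames + sb$n_frames
  m <- (sa$n_frames * sa$mean_delta + sb$n_frames * sb$mean_delta) / n
  v <- (sa$n_frames * (sa$std_delta^2 + sa$mean_delta^2) +
        sb$n_frames * (sb$std_delta^2 + sb$mean_delta^2)) / n - m^2
  expect_equal(sc$mean_delta, m, tolerance = 1e-12)
  expect_equal(sc$std_delta, sqrt(v), tolerance = 1e-12)
})

test_that("trajectory readers round-trip PDB and XYZ frames and the CSV dialect", {
  tr <- make_dihedral_frame(25, -5)
  # write multi-model PDB via bio3d and read back
  tmp <- tempfile(fileext = ".pdb")
  xyz1 <- as.numeric(t(tr$xyz[1, , ]))
  tf <- random_rigid_transform()
  xyz2 <- as.numeric(apply(tr$xyz[1, , ], 1, tf))
  bio3d::write.pdb(file = tmp, xyz = rbind(xyz1, xyz2),
                   type = rep("ATOM", 5),
                   resno = rep(66, 5), resid = rep("CRO", 5),
                   elety = tr$atoms$name)
  rd <- read_pdb_frames(tmp)
  expect_equal(dim(rd$xyz)[1], 2L)
  d <- chromophore_dihedrals(rd)
  expect_equal(d$phi_deg, c(25, 25), tolerance = 1e-2)  # PDB stores 3 decimals
  expect_equal(d$tau_deg, c(-5, -5), tolerance = 1e-2)

  # concatenated XYZ with two frames
  tmp2 <- tempfile(fileext = ".xyz")
  co <- tr$xyz[1, , ]
  lines <- c("5", "frame 1",
             sprintf("%s %f %f %f", tr$atoms$elem, co[, 1], co[, 2], co[, 3]),
             "5", "frame 2",
             sprintf("%s %f %f %f", tr$atoms$elem, co[, 1] + 1, co[, 2], co[, 3]))
  writeLines(lines, tmp2)
  rx <- read_xyz_frames(tmp2)
  expect_equal(dim(rx$xyz), c(2L, 5L, 3L))
  expect_equal(rx$xyz[2, , 1], co[, 1] + 1, tolerance = 1e-6)

  # dihedral CSV bypass recomputes wrapped Delta
  tmp3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_ps = c(0, 2.5), phi_deg = c(170, 30),
                       tau_deg = c(-150, 10)), tmp3, row.names = FALSE)
  dd <- read_dihedral_csv(tmp3)
  expect_equal(dd$delta_deg, c(-40, 20))
})
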