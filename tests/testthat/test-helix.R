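test_that("ideal helix builder reproduces textbook backbone geometry", {
  helix_axis_stats <- function(ca) {
    pc <- stats::prcomp(ca)
    proj <- pc$x[, 1]
    ang <- atan2(pc$x[, 3], pc$x[, 2])
    dang <- diff(ang); dang <- (dang + pi) %% (2 * pi) - pi
    list(rise = (max(proj) - min(proj)) / (nrow(ca) - 1),
         res_per_turn = 2 * pi / abs(mean(dang)))
  }
  a <- build_ideal_helix(18, -57, -47)
  sa <- helix_axis_stats(a$frames[[1]]$CA)
  expect_equal(sa$rise, 1.5, tolerance = 0.1)
  expect_equal(sa$res_per_turn, 3.6, tolerance = 0.25)
  g <- build_ideal_helix(18, -49, -26)
  sg <- helix_axis_stats(g$frames[[1]]$CA)
  expect_equal(sg$rise, 2.0, tolerance = 0.1)
  expect_equal(sg$res_per_turn, 3.1, tolerance = 0.25)
  # extended chain: end-to-end distance ~ n * 3.5 A
  e <- build_ideal_helix(12, 180, 180)
  ee <- sqrt(sum((e$frames[[1]]$CA[12, ] - e$frames[[1]]$CA[1, ])^2))
  expect_equal(ee / 11, 3.5, tolerance = 0.15)
  expect_error(build_ideal_helix(3, -57, -47), "n_res")
})

test_that("amide hydrogens are placed on the peptide-plane bisector at 1.01 A", {
  s <- place_amide_hydrogens(build_ideal_helix(10, -57, -47))
  f <- s$frames[[1]]
  for (i in 2:10) {
    expect_equal(sqrt(sum((f$H[i, ] - f$N[i, ])^2)), 1.01, tolerance = 1e-9)
  }
  expect_true(all(is.na(f$H[1, ])))  # no preceding carbonyl
  # existing hydrogens are retained, not overwritten
  s2 <- s
  s2$frames[[1]]$H[5, ] <- c(0, 0, 0)
  s2 <- place_amide_hydrogens(s2)
  expect_equal(s2$frames[[1]]$H[5, ], c(0, 0, 0))
  # ester sites never receive a hydrogen
  s3 <- place_amide_hydrogens(apply_ester(build_ideal_helix(10, -57, -47), 6))
  expect_true(all(is.na(s3$frames[[1]]$H[6, ])))
})

test_that("hydrogen-bond energy matches the point-charge formula and its cancellations", {
  # geometry constructed to give r_ON=2.9, r_CH=3.5, r_OH=1.9, r_CN=3.9
  N <- c(0, 0, 0); H <- c(0, 0, 1.01)
  z_O <- (8.41 - 3.61 + 1.01^2) / (2 * 1.01)
  O <- c(sqrt(8.41 - z_O^2), 0, z_O)
  z_C <- (15.21 - 12.25 + 1.01^2) / (2 * 1.01)
  C <- c(sqrt(15.21 - z_C^2), 0, z_C)
  expect_equal(sqrt(sum((O - N)^2)), 2.9, tolerance = 1e-12)
  expect_equal(sqrt(sum((O - H)^2)), 1.9, tolerance = 1e-12)
  expect_equal(sqrt(sum((C - N)^2)), 3.9, tolerance = 1e-12)
  expect_equal(sqrt(sum((C - H)^2)), 3.5, tolerance = 1e-12)
  e <- hbond_energy(list(N = N, H = H), list(C = C, O = O))
  oracle <- 27.888 * (1 / 2.9 + 1 / 3.5 - 1 / 1.9 - 1 / 3.9)
  expect_equal(e, oracle, tolerance = 1e-12)
  expect_equal(e, -4.24, tolerance = 0.01)
  # symmetric geometry (O and C equidistant from N and H) cancels exactly
  Hs <- c(1.01, 0, 0)
  Os <- c(0.505, 0, 2.8); Cs <- c(0.505, 1.2, 2.8)
  expect_equal(hbond_energy(list(N = N, H = Hs), list(C = Cs, O = Os)), 0,
               tolerance = 1e-12)
  # donor without hydrogen yields the no-energy sentinel, never numeric 0
  expect_true(is.na(hbond_energy(list(N = N, H = c(NA, NA, NA)),
                                 list(C = C, O = O))))
})

test_that("ideal fixtures classify as alpha, 3-10 and coil with the expected bond pattern", {
  sa <- place_amide_hydrogens(build_ideal_helix(14, -57, -47))
  hb <- backbone_hbonds(sa)
  expect_true(all(hb$k == 4))  # exclusively i+4 -> i bonds
  labs <- assign_secondary_structure(sa, hbonds = hb)
  expect_true(all(labs[2:13] == "H"))
  sg <- place_amide_hydrogens(build_ideal_helix(14, -49, -26))
  hbg <- backbone_hbonds(sg)
  expect_true(all(hbg$k == 3))
  labsg <- assign_secondary_structure(sg, hbonds = hbg)
  expect_true(all(labsg[2:13] == "G"))
  se <- place_amide_hydrogens(build_ideal_helix(14, 180, 180))
  expect_true(all(assign_secondary_structure(se) == "C"))
})

test_that("classification agrees with the brute-force pairwise oracle", {
  fixtures <- list(build_ideal_helix(15, -57, -47),
                   build_ideal_helix(15, -49, -26),
                   build_ideal_helix(15, -60, -30),  # between alpha and 3-10
                   build_ideal_helix(15, 180, 180))
  for (s in fixtures) {
    s <- place_amide_hydrogens(s)
    expect_identical(assign_secondary_structure(s), oracle_ss_labels(s))
  }
  # also with an ester in place
  se <- place_amide_hydrogens(apply_ester(build_ideal_helix(15, -57, -47), 8))
  expect_identical(assign_secondary_structure(se), oracle_ss_labels(se))
})

test_that("ester substitution removes exactly its own donor bond", {
  s <- place_amide_hydrogens(build_ideal_helix(12, -57, -47))
  before <- backbone_hbonds(s)
  se <- apply_ester(s, 7)
  after <- backbone_hbonds(se)
  expect_equal(nrow(before) - nrow(after), 1L)
  lost <- setdiff(paste(before$donor, before$acceptor),
                  paste(after$donor, after$acceptor))
  expect_identical(lost, "7 3")  # the 7 -> 7-4 alpha bond
  # every other bond is untouched
  kept <- before[paste(before$donor, before$acceptor) != "7 3", ]
  expect_equal(kept$energy,
               after$energy[match(paste(kept$donor, kept$acceptor),
                                  paste(after$donor, after$acceptor))])
  # ester at the N-terminus (no donor anyway) changes nothing
  sn <- apply_ester(s, 1)
  expect_equal(nrow(backbone_hbonds(sn)), nrow(before))
  # idempotence
  expect_equal(nrow(backbone_hbonds(apply_ester(se, 7))), nrow(after))
  expect_error(apply_ester(s, 99), "unknown")
})

test_that("energies and labels are invariant to rigid-body motion and renumbering", {
  s <- place_amide_hydrogens(build_ideal_helix(12, -57, -47))
  hb <- backbone_hbonds(s)
  R <- rotation_xyz(0.3, -1.2, 2.2)
  s2 <- transform_structure(s, R, shift = c(11, -3, 42))
  hb2 <- backbone_hbonds(s2)
  expect_equal(hb$energy, hb2$energy, tolerance = 1e-9)
  expect_identical(assign_secondary_structure(s),
                   assign_secondary_structure(s2))
  # residue renumbering offset leaves labels untouched
  s3 <- s; s3$resno <- s$resno + 356L
  expect_identical(assign_secondary_structure(s3),
                   assign_secondary_structure(s))
})

test_that("helical content aggregates per-residue class fractions over frames", {
  a <- place_amide_hydrogens(build_ideal_helix(12, -57, -47))
  g <- place_amide_hydrogens(build_ideal_helix(12, -49, -26))
  # 7 alpha frames + 3 three-ten frames = 70:30 mixture
  mix <- a
  mix$frames <- c(rep(a$frames, 7), rep(g$frames, 3))
  hc <- helical_content(mix)
  expect_true(all(abs(rowSums(hc[, c("H", "G", "I", "T", "C")]) - 1) < 1e-12))
  interior <- hc$resno %in% 2:11
  expect_equal(hc$H[interior], rep(0.7, sum(interior)))
  expect_equal(hc$G[interior], rep(0.3, sum(interior)))
  # all-alpha trajectory: interior alpha fraction 1
  hca <- helical_content(a)
  expect_true(all(hca$H[hca$resno %in% 2:11] == 1))
  expect_error(helical_content(a, residue_range = c(100, 120)), "empty")
})

test_that("multi-model PDB files round-trip through read_structure", {
  a <- place_amide_hydrogens(build_ideal_helix(8, -57, -47))
  g <- place_amide_hydrogens(build_ideal_helix(8, -49, -26))
  s <- a; s$frames <- c(a$frames, g$frames, a$frames, g$frames)
  path <- file.path(tempdir(), "helix4.pdb")
  write_structure_pdb(s, path)
  back <- read_structure(path)
  expect_equal(n_frames(back), 4L)
  expect_equal(n_residues(back), 8L)
  expect_equal(back$frames[[2]]$CA, g$frames[[1]]$CA, tolerance = 1e-3)
  # classification survives the round trip
  expect_identical(assign_secondary_structure(place_amide_hydrogens(back), 1),
                   assign_secondary_structure(a))
  # a residue missing its carbonyl oxygen is flagged unusable with a warning
  p_broken <- file.path(tempdir(), "broken.pdb")
  write_structure_pdb(a, p_broken)
  txt <- readLines(p_broken)
  drop <- grep("^ATOM.* O   ALA A   4", txt)[1]
  writeLines(txt[-drop], p_broken)
  expect_warning(broken <- read_structure(p_broken), "missing backbone")
  expect_false(broken$usable[4])
  # single-model minimal fixture
  m <- build_ideal_helix(4, -57, -47)
  p1 <- file.path(tempdir(), "mini.pdb")
  write_structure_pdb(m, p1)
  one <- read_structure(p1)
  expect_equal(n_frames(one), 1L)
  expect_equal(n_residues(one), 4L)
})

test_that("Shaker and chimera S4 numbering interconvert", {
  expect_identical(shaker_to_chimera(c(363L, 369L)), c(291L, 297L))
  expect_identical(chimera_to_shaker(shaker_to_chimera(360L)), 360L)
})
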