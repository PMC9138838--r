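test_that("flat planted bilayer is recovered perfectly", {
  sp <- membrane_spec(pm_comp(1 / 12), box = c(20, 20, 13),
                      undulation_amplitude = 0, seed = 5)
  gen <- build_membrane(sp)
  fr <- gen$trajectory$frames[[1]]
  al <- assign_leaflets(fr)
  m <- merge(al$lipid, gen$truth$leaflet_lipid, by = "resid")
  expect_identical(mean(m$leaflet.x == m$leaflet.y), 1)

  tm <- thickness_map(gen$trajectory)
  vals <- as.vector(tm)
  expect_true(all(vals[!is.na(vals)] == 4))
})

test_that("leaflets recover through 1 nm undulations at 2 nm offset", {
  sp <- membrane_spec(pm_comp(1 / 12), box = c(20, 20, 13),
                      undulation_amplitude = 1, undulation_modes = 2,
                      seed = 6)
  gen <- build_membrane(sp)
  al <- assign_leaflets(gen$trajectory$frames[[1]])
  m <- merge(al$lipid, gen$truth$leaflet_lipid, by = "resid")
  expect_gte(mean(m$leaflet.x == m$leaflet.y), 0.995)
})

test_that("a single-leaflet system labels everything outer", {
  n <- 50
  set.seed(2)
  pos <- cbind(runif(n, 0, 8), runif(n, 0, 8), rep(2, n))
  pos <- rbind(pos, cbind(runif(n, 0, 8), runif(n, 0, 8), rep(2.8, n)))
  fr <- frame(pos, rep("DAPE", 2 * n), rep(c("PO4", "C1A"), each = n),
              rep(seq_len(n), 2), c(8, 8, 6))
  al <- assign_leaflets(fr)
  expect_true(all(al$lipid$leaflet == "outer"))
})

test_that("density profile conserves bead count and finds planted peaks", {
  sp <- membrane_spec(pm_comp(1 / 12), box = c(20, 20, 13),
                      leaflet_z_offset = 2, seed = 9)
  gen <- build_membrane(sp, n_frames = 2)
  po4 <- species_selector(beads = "^PO4$", label = "PO4")
  prof <- density_profile(gen$trajectory, list(PO4 = po4), bin_width = 0.1)
  n_po4 <- sum(gen$trajectory$frames[[1]]$bead == "PO4")
  expect_equal(sum(prof$PO4), n_po4)  # exact conservation (mean per frame)
  # two symmetric peaks at +/- 2 nm within half a bin
  pk <- prof$z[order(prof$PO4, decreasing = TRUE)[1:2]]
  expect_equal(sort(pk), c(-2, 2), tolerance = 0.051)
})

test_that("uniform beads give a flat profile with exact integral", {
  set.seed(14)
  n <- 3000
  fr <- frame(cbind(runif(n, 0, 5), runif(n, 0, 5), runif(n, 0, 5)),
              rep("C60", n), rep("F1", n), seq_len(n), c(5, 5, 5))
  traj <- trajectory(list(fr))
  prof <- density_profile(traj, list(NP = species_selector(residues = "C60")),
                          bin_width = 0.5, center = FALSE)
  expect_equal(sum(prof$NP), n)
  inner <- prof$NP[prof$z > 0.5 & prof$z < 4.5]
  expect_lt(max(abs(inner - mean(inner))) / mean(inner), 0.3)
})

test_that("nanoparticles planted below the midplane peak on the inner side", {
  sp <- membrane_spec(pm_comp(1 / 12), box = c(20, 20, 13), np_count = 150,
                      seed = 10)
  gen <- build_membrane(sp)
  # shift all NP beads 1 nm below the midplane to emulate inner-leaflet
  # preference, then check the recovered density peak sits at negative z
  fr <- gen$trajectory$frames[[1]]
  np <- fr$resname == "C60"
  pos <- fr$positions
  pos[np, 3] <- pos[np, 3] - 1
  fr2 <- frame(pos, fr$resname, fr$bead, fr$resid, fr$box)
  prof <- density_profile(trajectory(list(fr2), gen$trajectory$composition),
                          list(NP = species_selector(residues = "C60")),
                          bin_width = 0.2)
  expect_lt(prof$z[which.max(prof$NP)], 0)
})

test_that("enrichment maps normalize to mean 1 and localize mass", {
  # all beads in one cell of a 2x2 grid -> that cell 4, others 0
  fr <- toy_frame(c(0.2, 0.2, 0.5, 0.3, 0.3, 0.5), box = c(2, 2, 2))
  em <- enrichment_map(trajectory(list(fr)),
                       species_selector(residues = "C60"), grid_spacing = 1)
  expect_equal(sort(as.vector(em)), c(0, 0, 0, 4))
  expect_equal(mean(em), 1, tolerance = 1e-12)

  set.seed(8)
  n <- 4000
  fru <- frame(cbind(runif(n, 0, 8), runif(n, 0, 8), rep(1, n)),
               rep("C60", n), rep("F1", n), seq_len(n), c(8, 8, 4))
  emu <- enrichment_map(trajectory(list(fru)),
                        species_selector(residues = "C60"), grid_spacing = 2)
  expect_equal(mean(emu), 1, tolerance = 1e-9)
  # uniform null: per-cell counts are Poisson(n/16); enrichment within 3 sigma
  expect_lt(max(abs(as.vector(emu) - 1)), 3 * sqrt(16 / n) * 1.5)
})

test_that("planted co-localization shows in enrichment map correlations", {
  comp <- balanced_comp()
  sp <- membrane_spec(comp, box = c(16, 16, 10), np_count = 120,
                      np_colocal_target = "DA", np_colocal_strength = 0.9,
                      seed = 12)
  gen <- build_membrane(sp, n_frames = 3)
  em_np <- enrichment_map(gen$trajectory, np_selector(comp), 2)
  em_da <- enrichment_map(gen$trajectory, tail_selector(comp, "DA"), 2)
  em_ch <- enrichment_map(gen$trajectory, sterol_selector(comp), 2)
  expect_gt(cor(as.vector(em_np), as.vector(em_da)), 0.5)
  expect_lt(cor(as.vector(em_np), as.vector(em_ch)), 0)
})

test_that("maps are invariant under rigid lateral translation modulo PBC", {
  comp <- balanced_comp()
  sp <- membrane_spec(comp, box = c(16, 16, 10), np_count = 60, seed = 13)
  gen <- build_membrane(sp)
  fr <- gen$trajectory$frames[[1]]
  shift <- c(4, 6, 0)  # whole cells at 2 nm spacing: cells permute exactly
  fr2 <- frame(sweep(fr$positions, 2, shift, `+`), fr$resname, fr$bead,
               fr$resid, fr$box)
  em1 <- enrichment_map(trajectory(list(fr)), np_selector(comp), 2)
  em2 <- enrichment_map(trajectory(list(fr2)), np_selector(comp), 2)
  expect_equal(sort(as.vector(em1)), sort(as.vector(em2)))
  tm1 <- thickness_map(trajectory(list(fr)), grid_spacing = 2)
  tm2 <- thickness_map(trajectory(list(fr2)), grid_spacing = 2)
  expect_equal(sort(as.vector(tm1)), sort(as.vector(tm2)))
})

test_that("thickness map recovers a planted bump under the cluster", {
  sp <- membrane_spec(balanced_comp(), box = c(16, 16, 10), np_count = 30,
                      cluster_fraction = 1, thickness_bump_amplitude = 0.5,
                      thickness_bump_sigma = 2, seed = 3)
  gen <- build_membrane(sp)
  tm <- thickness_map(gen$trajectory)
  g <- attr(tm, "grid")
  am <- which(unclass(tm) == max(tm, na.rm = TRUE), arr.ind = TRUE)[1, ]
  fr <- gen$trajectory$frames[[1]]
  incl <- fr$resid %in% gen$truth$cluster_members
  ctr <- colMeans(fr$positions[incl, 1:2, drop = FALSE])
  d <- abs((am - 0.5) * g$spacing - ctr)
  d <- pmin(d, c(16, 16) - d)
  expect_true(all(d <= 2 * g$spacing))
})

test_that("grid spacing larger than the box pools to the global mean", {
  sp <- membrane_spec(balanced_comp(), box = c(16, 16, 10), seed = 4)
  gen <- build_membrane(sp)
  tm <- thickness_map(gen$trajectory, grid_spacing = 50)
  expect_equal(dim(tm), c(1L, 1L))
  expect_equal(as.vector(tm), 4, tolerance = 1e-9)
})

test_that("undulation metrics recover planted modes and amplitudes", {
  sp0 <- membrane_spec(balanced_comp(), box = c(16, 16, 10),
                       undulation_amplitude = 0, seed = 2)
  um0 <- undulation_metric(build_membrane(sp0)$trajectory)
  expect_lt(um0$rms, 1e-6)

  sp2 <- membrane_spec(pm_comp(1 / 3), box = c(40, 40, 13),
                       undulation_amplitude = 0.8, undulation_modes = 2,
                       seed = 7)
  gen2 <- build_membrane(sp2)
  um2 <- undulation_metric(gen2$trajectory)
  pm <- gen2$truth$undulation_modes
  top2 <- um2$spectrum[1:2, c("p", "q")]
  expect_setequal(paste(top2$p, top2$q), paste(pm$p, pm$q))
  for (j in 1:2) {
    rec <- um2$spectrum$amplitude[um2$spectrum$p == pm$p[j] &
                                    um2$spectrum$q == pm$q[j]]
    expect_equal(rec, pm$amplitude[j], tolerance = 0.05)
  }
})

test_that("unsaturation histogram tallies, normalizes and orders leaflets", {
  two <- composition(data.frame(
    residue = c("DAPE", "DPPC"), headgroup = c("PE", "PC"),
    tail1 = c("DA", "DP"), tail2 = c("DA", "DP"),
    db1 = c(4, 0), db2 = c(4, 0),
    leaflet = c("inner", "outer"), count = c(100, 80)))
  uh <- unsaturation_histogram(two)
  expect_equal(uh$inner[uh$db == 4], 1)
  expect_equal(uh$outer[uh$db == 0], 1)
  expect_equal(sum(uh$inner), 1, tolerance = 1e-9)
  expect_equal(sum(uh$outer), 1, tolerance = 1e-9)

  pm <- pm_comp()
  uhp <- unsaturation_histogram(pm)
  expect_equal(sum(uhp$inner), 1, tolerance = 1e-9)
  mean_db <- function(v) sum(uhp$db * v)
  # the asymmetric composition concentrates polyunsaturated tails inside
  expect_gt(mean_db(uhp$inner), mean_db(uhp$outer))

  empty <- composition(data.frame(
    residue = "DPPC", headgroup = "PC", tail1 = "DP", tail2 = "DP",
    db1 = 0, db2 = 0, leaflet = "outer", count = 10))
  expect_error(unsaturation_histogram(empty), "inner")
})
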