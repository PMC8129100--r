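test_that("CCDP is a probability-normalised histogram with bin-centre peaks", {
  p1 <- ccdp(30)
  expect_equal(sum(p1$probabilities), 1)
  expect_equal(p1$probabilities[7], 1) # bin [30, 35)
  expect_equal(ccdp_peak(p1), 32.5)
  # three collinear cells at 0, 50, 100: pairs 50, 50, 100
  p2 <- ccdp(as.numeric(dist(c(0, 50, 100))))
  expect_equal(p2$probabilities[11], 2 / 3) # [50, 55)
  expect_equal(p2$probabilities[21], 1 / 3) # [100, 105)
  expect_equal(ccdp_peak(p2), 52.5)
  expect_error(ccdp(numeric(0)), "at least one")
  # mass conservation on random inputs
  set.seed(1)
  for (q in 1:5) {
    p <- ccdp(runif(200, 0, 300))
    expect_equal(sum(p$probabilities), 1, tolerance = 1e-9)
  }
})

test_that("CCDP peaks land on 5-um bin centres and ties break low", {
  p <- ccdp(c(72, 72, 93, 93)) # bins [70,75) and [90,95) tie at 2 each
  expect_equal(ccdp_peak(p), 72.5)
  p2 <- ccdp(c(71, 72, 73))
  expect_equal(ccdp_peak(p2), 72.5)
})

test_that("cluster segmentation separates Gaussian blobs at their midpoint", {
  set.seed(8)
  pop <- make_cell_field("clusters", n = 10000, box = c(2000, 200, 100),
                         centers = c(500, 1500), sigma = 100, seed = 8)
  seg <- segment_clusters(pop)
  expect_equal(length(seg$cluster_intervals), 2)
  boundary <- seg$cluster_intervals[[1]][2]
  expect_lt(abs(boundary - 1000), 50)
  # single blob
  pop1 <- make_cell_field("clusters", n = 10000, box = c(1000, 200, 100),
                          centers = 500, sigma = 80, seed = 9)
  expect_equal(length(segment_clusters(pop1)$cluster_intervals), 1)
  expect_error(
    segment_clusters(cell_population(rbind(c(1, 1, 1)), "A")),
    "no neurons")
})

test_that("cluster CCDP reduces to the plain CCDP in one z-bin and counts pairs per z-bin", {
  set.seed(3)
  one_cluster <- function(xmax) {
    structure(list(cluster_intervals = list(c(0, xmax)),
                   culture_extent = c(0, xmax), bin_width_x = 10,
                   bin_centers = numeric(0), counts = numeric(0)),
              class = "cluster_segmentation")
  }
  # all cells within one 10-um z-slab, one cluster
  pos <- cbind(runif(60, 0, 300), runif(60, 0, 200), runif(60, 2, 8))
  pop <- cell_population(pos, rep("N", 60))
  cc <- cluster_ccdp(pop, one_cluster(301))
  planar <- ccdp(as.numeric(dist(pos[, 1:2])))
  expect_equal(cc$mean_profile$probabilities, planar$probabilities)
  # two z-bins: pair count must match per-bin enumeration
  pos2 <- cbind(runif(80, 0, 300), runif(80, 0, 200),
                sample(c(2, 15), 80, replace = TRUE))
  pop2 <- cell_population(pos2, rep("N", 80))
  cc2 <- cluster_ccdp(pop2, one_cluster(301))
  expect_equal(cc2$profiles[[1]]$n_distances, oracle_zbin_pairs(pos2))
})

test_that("cluster CCDP pair counts match brute force on larger mixed instances", {
  set.seed(12)
  pos <- cbind(runif(180, 0, 500), runif(180, 0, 200), runif(180, 0, 40))
  pop <- cell_population(pos, rep("N", 180))
  seg <- segment_clusters(pop)
  cc <- cluster_ccdp(pop, seg)
  # total pooled distances across clusters = brute-force z-bin pair count
  # restricted to within-cluster pairs
  total <- 0
  for (ci in seq_along(seg$cluster_intervals)) {
    iv <- seg$cluster_intervals[[ci]]
    sub <- pos[pos[, 1] >= iv[1] & pos[, 1] < iv[2], , drop = FALSE]
    if (nrow(sub) >= 2) total <- total + oracle_zbin_pairs(sub)
  }
  expect_equal(sum(vapply(cc$profiles, `[[`, numeric(1), "n_distances")),
               total)
})

test_that("the mean of identical profiles is the profile itself", {
  p <- ccdp(c(10, 30, 30, 80))
  m <- mean_ccdp(list(p, p, p))
  expect_equal(m$probabilities, p$probabilities)
  expect_equal(sum(m$probabilities), 1, tolerance = 1e-12)
})

test_that("contraction is the relative shortening of the robust x-extent", {
  mk <- function(L, n = 2000) {
    set.seed(1)
    cell_population(cbind(seq(0, L, length.out = n), runif(n, 0, 200),
                          runif(n, 0, 100)), rep("N", n))
  }
  expect_equal(contraction(mk(4000), mk(3000)), 25, tolerance = 0.5)
  p <- mk(1000)
  expect_equal(contraction(p, p), 0)
  expect_equal(normalized_contraction(24, c(30, 30, 30)), 0.8)
  expect_error(normalized_contraction(10, c(0, 0)), "reference")
})

test_that("depth profile recovers constructed shell and uniform mixtures", {
  shell <- make_cell_field("shell", n = 4000, box = c(1000, 200, 50),
                           shell_thickness = 10, shell_fraction = 0.9,
                           core_fraction = 0.02, seed = 2)
  dp <- depth_profile(shell)
  expect_gt(dp$superficial_ratio, dp$deep_max_ratio)
  uni <- make_cell_field("uniform", n = 6000, box = c(500, 500, 100),
                         astrocyte_fraction = 0.2, seed = 3)
  dpu <- depth_profile(uni)
  counts <- dpu$total_count
  ok <- counts >= 50
  sigma3 <- 3 * sqrt(0.2 * 0.8 / counts[ok])
  expect_true(all(abs(dpu$astrocyte_ratio[ok] - 0.2) <= sigma3 + 0.02))
})

test_that("depth scalars are invariant under rigid translation", {
  pop <- make_cell_field("shell", n = 2000, box = c(600, 200, 60), seed = 5)
  dp0 <- depth_profile(pop)
  shifted <- cell_population(
    sweep(pop$positions, 2, c(137.3, 41.9, 53.1), `+`), pop$types)
  dp1 <- depth_profile(shifted)
  expect_lt(abs(dp1$superficial_ratio - dp0$superficial_ratio), 0.02)
  expect_lt(abs(dp1$deep_max_ratio - dp0$deep_max_ratio), 0.05)
})

test_that("force-morphology correlations behave like Pearson correlations", {
  AS <- expand.grid(AS_NN = c(1, 0.9), AS_NA = c(1, 0.9),
                    AS_AN = c(1, 0.9), AS_AA = 1)
  tab <- cbind(AS, superficial_astro_ratio = AS$AS_NN)
  r <- force_morphology_correlation(tab)
  expect_equal(unname(r["NN"]), 1)
  expect_true(is.na(r["AA"])) # zero-variance column
  # shuffled columns decorrelate on average (permutation oracle)
  set.seed(6)
  rs <- replicate(200, {
    t2 <- tab
    t2$superficial_astro_ratio <- sample(runif(nrow(t2)))
    force_morphology_correlation(t2)["NN"]
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(force_morphology_correlation(tab[1:2, ]), "three")
})

test_that("radial density profiles expose rings and central clusters", {
  set.seed(4)
  # synthetic annulus: neurons at radii ~ 300 of a 400-radius disk
  n <- 3000
  th <- runif(n, 0, 2 * pi)
  r <- rnorm(n, 300, 20)
  pop <- cell_population(cbind(r * cos(th), r * sin(th), runif(n, 0, 50)),
                         rep("N", n))
  prof <- radial_density_profile(pop)
  expect_gt(prof$r_center[which.max(prof$density)], 200)
  # uniform disk: peak density is not at an outer annulus
  r2 <- 400 * sqrt(runif(n))
  pop2 <- cell_population(cbind(r2 * cos(th), r2 * sin(th),
                                runif(n, 0, 50)), rep("N", n))
  prof2 <- radial_density_profile(pop2)
  inner <- prof2$density[prof2$r_center < 200]
  outer <- prof2$density[prof2$r_center >= 200]
  expect_lt(max(outer) / max(inner), 1.5)
})
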