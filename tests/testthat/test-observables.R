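test_that("coverage accounting integrates to footprint * bound time", {
  # one molecule that never unbinds covers exactly `footprint` bp at all
  # times, so the coverage fractions must sum to the footprint
  cfg <- flat_config(M = 200, copies = 1, k_assoc = 1e5, p_unbind = 0,
                     tau0 = 1e-5, duration = 1, record_occupancy = TRUE)
  tr <- simulate_fd(cfg, seed = 21)
  cov <- coverage_profile(tr, species = "walker")
  expect_equal(sum(cov), 23, tolerance = 1e-3)  # binds within ~10 us
  expect_true(all(cov <= 1 + 1e-12))
  bias <- occupancy_bias(cov)
  expect_true(bias$normalized)
  expect_equal(mean(bias$bias), 1)
})

test_that("zero coverage yields an unnormalized flagged profile", {
  cfg <- flat_config(M = 200, copies = 1, k_assoc = 0, duration = 0.1,
                     record_occupancy = TRUE)
  tr <- simulate_fd(cfg, seed = 22)
  bias <- occupancy_bias(tr, species = "walker")
  expect_false(bias$normalized)
  expect_true(all(bias$bias == 0))
})

test_that("profile correlation behaves at its fixed points and null", {
  x <- c(0.2, 1.4, 0.9, 2.0, 0.5)
  p <- occupancy_bias(x)
  expect_equal(occupancy_correlation(list(p), x), 1)
  expect_equal(occupancy_correlation(list(occupancy_bias(2 * mean(x) - x)),
                                     x), -1)
  expect_true(is.na(occupancy_correlation(list(rep(1, 5)), x)))
  # two independent flat-landscape replicates decorrelate
  cfg <- flat_config(M = 20000, copies = 10, k_assoc = 5000,
                     p_unbind = 0.02, tau0 = 1e-5, duration = 5,
                     record_occupancy = TRUE)
  covs <- run_replicates(cfg, 2, base_seed = 23, summarize = function(tr)
    coverage_profile(tr, species = "walker"))
  r <- cor(covs[[1]], covs[[2]])
  expect_lt(abs(r), 0.15)  # ~3 sigma with ~23 bp footprint autocorrelation
})

# Two-site toy: a perfect A6 site and a two-mismatch site planted in a
# C/G-rich background (A-runs essentially never occur by chance), with
# non-A flanks so the planted window is a strict local maximum. The
# footprint equals the motif length, and the per-start occupied-time
# vector is used as the occupancy (no footprint smear), which makes the
# Boltzmann stationary law exact: time at start j ~ exp(E_j).
two_site_system <- function(copies, duration, tau0 = 1e-6,
                            p_unbind = 0.05) {
  bg <- nt_background(0.15, 0.35, 0.35, 0.15)
  pfm <- build_pfm(c("AAAAAA", "AAAAAA"), zeta = 1, bg = bg)
  g <- synthesize_genome(3000, bg = bg, seed = 31)
  g <- plant_site(g, "CAAAAAAG", 999, "strong")   # perfect site at 1000
  g <- plant_site(g, "CAACAACG", 1999, "weak")    # two mismatches at 2000
  sp <- tf_species("tf", copies, footprint = 6L, tau0 = tau0,
                   k_assoc = 2000, p_unbind = p_unbind)
  cfg <- sim_config(g, sp, pfm = pfm, duration = duration,
                    record_occupancy = TRUE)
  list(cfg = cfg, g = g, pfm = pfm)
}

start_dwell <- function(tr) tr$occupancy[["tf"]] / tr$duration

test_that("affinity/occupancy ratios approach 1 at low-copy equilibrium", {
  # Boltzmann oracle: stationary occupancy ~ exp(E), so normalized
  # affinity and occupancy agree site by site
  ts <- two_site_system(copies = 1, duration = 40)
  tr <- simulate_fd(ts$cfg, seed = 32)
  ls <- score_landscape(ts$g, ts$pfm)
  ss <- affinity_occupancy_ratio(start_dwell(tr), ls,
                                 threshold_frac = 0.35)
  strong <- ss[ss$position == 1000 & ss$strand == "+", ]
  weak <- ss[ss$position == 2000 & ss$strand == "+", ]
  expect_equal(nrow(strong), 1)
  expect_equal(nrow(weak), 1)
  expect_lt(abs(strong$ratio - 1), 0.25)
  expect_lt(abs(weak$ratio - 1), 0.3)
})

test_that("crowding pushes weak-site ratios below one (false positives)", {
  ts <- two_site_system(copies = 250, duration = 1.5, tau0 = 2e-5)
  tr <- simulate_fd(ts$cfg, seed = 33)
  ls <- score_landscape(ts$g, ts$pfm)
  ss <- affinity_occupancy_ratio(start_dwell(tr), ls,
                                 threshold_frac = 0.35)
  strong <- ss[ss$position == 1000 & ss$strand == "+", ]
  weak <- ss[ss$position == 2000 & ss$strand == "+", ]
  # saturated occupancy flattens: the strong site is occupied less than
  # its affinity share predicts, the weak one more
  expect_gt(strong$ratio, 1)
  expect_lt(weak$ratio, 1)
})

test_that("a single site in the threshold set has ratio exactly 1", {
  ts <- two_site_system(copies = 1, duration = 2)
  tr <- simulate_fd(ts$cfg, seed = 34)
  ls <- score_landscape(ts$g, ts$pfm)
  ss <- affinity_occupancy_ratio(start_dwell(tr), ls, threshold_frac = 0)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$ratio, 1)
  expect_error(affinity_occupancy_ratio(start_dwell(tr), ls,
                                        threshold_frac = -1),
               "empty site set")
})

test_that("residence time scales inversely with the unbinding probability", {
  t_R <- vapply(c(1e-2, 1e-3), function(pd) {
    cfg <- flat_config(copies = 1, p_unbind = pd, tau0 = 1e-5,
                       k_assoc = 5000, duration = 10)
    one_dim_stats(simulate_fd(cfg, seed = 35))$t_R
  }, numeric(1))
  expect_equal(t_R[2] / t_R[1], 10, tolerance = 0.15)
  # p_unbind = 1: single-step visits, sl_obs = sqrt(2)
  cfg1 <- flat_config(copies = 1, p_unbind = 1, k_assoc = 5000,
                      duration = 0.5)
  st <- one_dim_stats(simulate_fd(cfg1, seed = 36))
  expect_equal(st$n_steps, 1)
  expect_equal(st$sl_obs, sqrt(2))
})

test_that("bedGraph export run-length encodes the profile", {
  v <- c(0, 0, 1, 1, 0.5)
  tf <- tempfile(fileext = ".bedGraph")
  write_bedgraph(v, tf, chrom = "chr", offset = 10)
  b <- read.table(tf)
  expect_equal(nrow(b), 3)
  expect_equal(b$V2, c(10, 12, 14))
  expect_equal(b$V3, c(12, 14, 15))
})
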