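test_that("an empty system produces an empty trajectory", {
  cfg <- flat_config(copies = 0, duration = 0.5, record_occupancy = TRUE)
  tr <- simulate_fd(cfg, seed = 1)
  expect_equal(tr$species$n_visits, 0)
  expect_equal(tr$species$bound_time, 0)
  expect_equal(tr$n_events, 0)
  expect_true(all(tr$occupancy[[1]] == 0))
})

test_that("p_unbind = 1 makes every visit a single event", {
  cfg <- flat_config(copies = 3, p_unbind = 1, k_assoc = 5000,
                     duration = 0.5, max_visit_records = 10000)
  tr <- simulate_fd(cfg, seed = 2)
  expect_gt(nrow(tr$visits), 100)
  expect_true(all(tr$visits$steps == 1))
  expect_true(all(tr$visits$bind_pos == tr$visits$unbind_pos))
})

test_that("visit lengths follow the geometric law on a flat landscape", {
  pd <- 0.02
  cfg <- flat_config(copies = 1, p_unbind = pd, tau0 = 1e-5,
                     k_assoc = 5000, duration = 30,
                     max_visit_records = 100000)
  tr <- simulate_fd(cfg, seed = 3)
  n <- tr$visits$steps
  expect_gt(length(n), 1e4)
  # mean = 1/p within 3 standard errors (sd of geometric ~ sqrt(1-p)/p)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - 1 / pd), 3 * se)
  # chi-squared against Geometric(pd), binned with expected counts >= 5
  brk <- c(seq(0, 4 / pd, by = 0.5 / pd), Inf)
  obs <- table(cut(n, brk))
  p_bin <- diff(pgeom(brk - 1, pd))  # steps = 1 + geom(number of failures)
  p_bin[length(p_bin)] <- 1 - sum(p_bin[-length(p_bin)])
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = p_bin))
  expect_gt(chi$p.value, 0.001)
  # mean dwell per visit ~ tau0 / pd
  st <- one_dim_stats(tr)
  expect_lt(abs(st$t_R - 1e-5 / pd) / (1e-5 / pd), 0.05)
})

test_that("single-molecule bound fraction matches the renewal closed form", {
  # alternating renewal: f = k t_R / (1 + k t_R) with t_R = tau0 / p_unbind;
  # a single molecule on an empty lattice has A_free/A_total = 1 while free
  k <- 2000; pd <- 0.02; tau0 <- 1e-5
  tR <- tau0 / pd
  f_true <- k * tR / (1 + k * tR)
  cfg <- flat_config(copies = 1, k_assoc = k, p_unbind = pd, tau0 = tau0,
                     duration = 3)
  fs <- vapply(run_replicates(cfg, 10, base_seed = 4),
               function(tr) estimate_f(tr)$f, numeric(1))
  se <- sd(fs) / sqrt(length(fs))
  expect_lt(abs(mean(fs) - f_true), 3 * se)
})

test_that("molecule count is conserved and exclusion holds at every event", {
  # crowded flat system with per-event invariant checks compiled in
  g <- synthesize_genome(2000, seed = 6)
  sp <- list(tf_species("a", 20, footprint = 23, tau0 = 1e-5, k_assoc = 500,
                        p_unbind = 0.01, cognate = FALSE),
             tf_species("b", 30, footprint = 11, tau0 = 2e-5, k_assoc = 300,
                        p_unbind = 0.02, cognate = FALSE))
  cfg <- sim_config(g, sp, duration = 1, check_invariants = TRUE)
  tr <- simulate_fd(cfg, seed = 6)
  expect_equal(tr$violations, 0)
  expect_gt(tr$n_events, 1e4)
})

test_that("occupancy flattens toward uniform on a flat landscape", {
  mk <- function(d) flat_config(M = 2000, copies = 5, k_assoc = 2000,
                                p_unbind = 0.05, tau0 = 1e-5, duration = d,
                                record_occupancy = TRUE)
  cv <- vapply(c(2, 20), function(d) {
    cov <- coverage_profile(simulate_fd(mk(d), seed = 7), species = "walker")
    interior <- cov[100:1900]
    sd(interior) / mean(interior)
  }, numeric(1))
  expect_lt(cv[2], cv[1])      # longer run, flatter profile
  expect_lt(cv[2], 0.2)
})

test_that("replicates are reproducible and streams are distinct", {
  cfg <- flat_config(copies = 2, duration = 0.2, max_visit_records = 1000)
  a <- run_replicates(cfg, 3, base_seed = 11)
  b <- run_replicates(cfg, 3, base_seed = 11)
  for (i in 1:3) {
    expect_identical(a[[i]]$species, b[[i]]$species)
    expect_identical(a[[i]]$visits, b[[i]]$visits)
  }
  expect_false(identical(a[[1]]$visits, a[[2]]$visits))
  # summarize hook stores the reduced value
  s <- run_replicates(cfg, 2, base_seed = 11,
                      summarize = function(tr) tr$n_events)
  expect_equal(s[[1]], a[[1]]$n_events)
})

test_that("configuration validation catches bad systems", {
  g <- synthesize_genome(100, seed = 8)
  sp <- tf_species("x", 10, footprint = 23, cognate = FALSE)
  expect_error(sim_config(g, sp, duration = 1), "over-packed")
  expect_error(sim_config(g, tf_species("x", 1), duration = 1), "pfm")
  expect_error(flat_config(duration = -1), "duration")
  expect_error(tf_species("x", 1, p_unbind = 2), "p_unbind")
})

test_that("a target is tracked: censoring and occupancy accounting", {
  g <- small_lac_genome(2000, seed = 9, pos = 1000)
  pfm <- lacI_pfm()
  # k_assoc = 0: molecule never binds, first passage censored
  sp <- tf_species("lacI", 1, k_assoc = 0)
  cfg <- sim_config(g, sp, pfm = pfm, target = "O1", duration = 0.1)
  tr <- simulate_fd(cfg, seed = 10)
  fp <- first_passage_time(tr)
  expect_true(fp$censored)
  expect_equal(fp$time, 0.1)
  expect_equal(target_occupancy_probability(tr), 0)
})

test_that("target occupancy on a one-site lattice matches renewal theory", {
  # sequence exactly one footprint long: every binding lands on the target,
  # so occupancy probability = t_R / (t_R + 1/k)
  pfm <- lacI_pfm()
  seq23 <- paste0("A", lacI_sites(FALSE)[["O1"]], "A")
  g <- genome_seq(seq23)
  g <- plant_site(g, lacI_sites(FALSE)[["O1"]], 2, "O1")
  k <- 500; pd <- 0.5; tau0 <- 1e-6
  sp <- tf_species("lacI", 1, footprint = 23, tau0 = tau0, k_assoc = k,
                   p_unbind = pd)
  cfg <- sim_config(g, sp, pfm = pfm, target = "O1", duration = 5)
  dwell <- cfg$cpp_species[[1]]$dwell_fwd[1]  # tau0 * exp(E) at the site
  dwell_r <- cfg$cpp_species[[1]]$dwell_rev[1]
  tR <- 0.5 * (dwell + dwell_r) / pd  # strand chosen uniformly at binding
  p_true <- tR / (tR + 1 / k)
  ps <- vapply(run_replicates(cfg, 10, base_seed = 12),
               target_occupancy_probability, numeric(1))
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - p_true), 3 * se)
  # first passage happened and molecule was on target when bound
  tr <- simulate_fd(cfg, seed = 13)
  expect_false(first_passage_time(tr)$censored)
})
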