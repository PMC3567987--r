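#' Synthetic lac-region genome
#'
#' An i.i.d. random sequence at the E. coli base composition with the
#' three lac operators planted at their native relative offsets: O1 at
#' the requested position (default the sequence midpoint), O3 92 bp
#' upstream and O2 401 bp downstream of the O1 start. This emulates a
#' genomic region around the lac operon; it reproduces the background
#' energy statistics and the operator cluster, but none of the long-range
#' correlation structure of a real genome.
#'
#' @param length Sequence length in bp.
#' @param seed Integer seed for the background sequence.
#' @param o1_position 1-based start of O1 (default: centered).
#' @param bg An `nt_background`.
#' @return A `genome_seq` with annotations `O1`, `O2`, `O3`.
#' @export
lac_region_genome <- function(length, seed = 1L,
                              o1_position = round(length / 2),
                              bg = ecoli_background()) {
  ops <- lacI_sites(gapped = FALSE)
  g <- synthesize_genome(length, bg = bg, seed = seed, name = "lac_region")
  g <- plant_site(g, ops[["O3"]], o1_position - 92L, "O3")
  g <- plant_site(g, ops[["O1"]], o1_position, "O1")
  plant_site(g, ops[["O2"]], o1_position + 401L, "O2")
}

#' The lac repressor parameterization of the full system
#'
#' Species list for the genome-scale reference configuration: 1000
#' cognate lacI tetramers and 50000 non-cognate crowder molecules, both
#' with 23 bp footprints and association rate 2400 /s, lacI with
#' `tau0 = 1.18e-6` s and unbinding probability 2.7e-4.
#'
#' @param cognate_copies,noncognate_copies Copy numbers.
#' @return List of two `tf_species`.
#' @export
lacI_species_full <- function(cognate_copies = 1000L,
                              noncognate_copies = 50000L) {
  list(tf_species("lacI", cognate_copies, cognate = TRUE),
       tf_species("crowder", noncognate_copies, cognate = FALSE))
}

#' Full-system versus subsystem equivalence experiment
#'
#' Runs the complete comparison protocol behind the system-size-reduction
#' claim: a "full" system and a subsystem extracted around the O1 target,
#' simulated under (i) copy-number scaling, (ii) association-rate scaling
#' and (iii) no adjustment at all (negative control), with only cognate
#' lacI molecules present. For every replicate of every system it
#' records, on the common window corresponding to the subsystem, the
#' occupancy-bias correlation to the mean full-system profile, the first
#' passage time to O1 and the O1 occupancy probability; pooled 1D
#' statistics (t_R, sliding length, f) are kept per system.
#'
#' The bound-time fraction `f` used by the association-rate model is
#' estimated from the full-system replicates themselves (at least 20 are
#' recommended).
#'
#' @param full_size,sub_size Genome sizes in bp.
#' @param copies Cognate copy number in the full system.
#' @param duration Simulated seconds per replicate (same for every
#'   system, so distributions are comparable).
#' @param n_reps Replicates per system.
#' @param base_seed Integer seed; genome and replicate streams derive
#'   from it.
#' @param systems Character subset of
#'   `c("full", "copy_number", "assoc_rate", "unadjusted")`.
#' @param k_assoc Full-system association rate.
#' @return Object of class `equivalence_result`: `$metrics` (one row per
#'   system x replicate: `r`, `fpt`, `censored`, `p_occ`), `$stats`
#'   (pooled `one_dim_stats` per system), `$f_full`, `$lambda`,
#'   `$gamma`, `$copies`, `$window`.
#' @export
subsystem_equivalence <- function(full_size = 460000, sub_size = 46000,
                                  copies = 10L, duration = 10,
                                  n_reps = 60L, base_seed = 1L,
                                  systems = c("full", "copy_number",
                                              "assoc_rate", "unadjusted"),
                                  k_assoc = 2400) {
  systems <- match.arg(systems, several.ok = TRUE)
  pfm <- build_pfm(lacI_sites())
  full <- lac_region_genome(full_size, seed = base_seed)
  sub <- extract_subsystem(full, "O1", sub_size)
  lambda <- sub_size / full_size
  offset <- attr(sub, "offset")
  window_full <- c(offset, offset + sub_size - 1L)

  run_system <- function(genome, sp, window, seed_shift) {
    cfg <- sim_config(genome, sp, pfm = pfm, target = "O1",
                      duration = duration, record_occupancy = TRUE)
    run_replicates(cfg, n_reps, base_seed = base_seed + seed_shift,
                   summarize = function(tr) {
                     list(cov = coverage_profile(tr, "lacI", window),
                          fpt = first_passage_time(tr),
                          p_occ = target_occupancy_probability(tr),
                          species = tr$species, duration = tr$duration,
                          M = tr$M)
                   })
  }
  pool_stats <- function(reps) {
    one_dim_stats(lapply(reps, function(x)
      structure(list(species = x$species, duration = x$duration),
                class = "sim_trajectory")), species = "lacI")
  }

  sp_full <- list(tf_species("lacI", copies, k_assoc = k_assoc))
  res <- list()
  full_reps <- run_system(full, sp_full, window_full, 0L)
  f_full <- pool_stats(full_reps)$f
  gamma <- scale_assoc_rate(k_assoc, lambda, f_full)$gamma
  if ("full" %in% systems) res$full <- full_reps
  if ("copy_number" %in% systems)
    res$copy_number <- run_system(
      sub, reduce_species(sp_full, lambda, "copy_number"),
      c(1L, sub_size), 1000L)
  if ("assoc_rate" %in% systems)
    res$assoc_rate <- run_system(
      sub, reduce_species(sp_full, lambda, "assoc_rate", f = f_full),
      c(1L, sub_size), 2000L)
  if ("unadjusted" %in% systems)
    res$unadjusted <- run_system(sub, sp_full, c(1L, sub_size), 3000L)

  reference <- mean_bias_profile(lapply(full_reps, function(x)
    occupancy_bias(x$cov)))
  metrics <- do.call(rbind, lapply(names(res), function(nm) {
    reps <- res[[nm]]
    per_rep <- lapply(reps, function(x) {
      one_dim_stats(structure(list(species = x$species,
                                   duration = x$duration),
                              class = "sim_trajectory"), species = "lacI")
    })
    data.frame(
      system = nm, rep = seq_along(reps),
      r = occupancy_correlation(lapply(reps, function(x)
        occupancy_bias(x$cov)), reference),
      fpt = vapply(reps, function(x) x$fpt$time, numeric(1)),
      censored = vapply(reps, function(x) x$fpt$censored, logical(1)),
      p_occ = vapply(reps, function(x) x$p_occ, numeric(1)),
      f = vapply(per_rep, `[[`, numeric(1), "f"),
      t_R = vapply(per_rep, `[[`, numeric(1), "t_R"),
      sl_obs = vapply(per_rep, `[[`, numeric(1), "sl_obs"),
      bound_per_bp = vapply(reps, function(x) {
        st <- x$species
        row <- which(st$name == "lacI")
        st$bound_time[row] / x$duration / x$M
      }, numeric(1)))
  }))
  structure(list(metrics = metrics,
                 stats = lapply(res, pool_stats),
                 f_full = f_full, lambda = lambda, gamma = gamma,
                 copies = copies, window = window_full,
                 duration = duration, n_reps = n_reps),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "equivalence_result: lambda = %.3g, f_full = %.3f, gamma = %.4g\n",
    x$lambda, x$f_full, x$gamma))
  agg <- aggregate(cbind(r, fpt, p_occ) ~ system, data = x$metrics, mean)
  print(agg)
  invisible(x)
}

#' Two-sample comparison of a subsystem against the full system
#'
#' Kolmogorov-Smirnov p-values for the occupancy-bias correlation and
#' first-passage-time distributions (censored passages excluded from the
#' KS sample), and the difference in mean target-occupancy probability in
#' units of its standard error.
#'
#' @param result An `equivalence_result`.
#' @param system One of the subsystem names in `result$metrics`.
#' @return List with `ks_r`, `ks_fpt` (p-values), `z_occ` (standardized
#'   mean difference), and the underlying means.
#' @export
compare_to_full <- function(result, system) {
  m <- result$metrics
  a <- m[m$system == "full", ]
  b <- m[m$system == system, ]
  if (nrow(b) == 0) stop("system '", system, "' not present")
  ks_r <- suppressWarnings(
    stats::ks.test(a$r[!is.na(a$r)], b$r[!is.na(b$r)]))$p.value
  ks_fpt <- suppressWarnings(
    stats::ks.test(a$fpt[!a$censored], b$fpt[!b$censored]))$p.value
  se <- sqrt(stats::var(a$p_occ) / nrow(a) + stats::var(b$p_occ) / nrow(b))
  list(ks_r = ks_r, ks_fpt = ks_fpt,
       z_occ = (mean(b$p_occ) - mean(a$p_occ)) / se,
       mean_occ_full = mean(a$p_occ), mean_occ_sub = mean(b$p_occ),
       mean_fpt_full = mean(a$fpt[!a$censored]),
       mean_fpt_sub = mean(b$fpt[!b$censored]))
}
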