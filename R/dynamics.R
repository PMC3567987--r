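#' Transcription-factor species parameters
#'
#' Kinetic and geometric parameters of one molecule type. Cognate species
#' draw their 1D waiting times from the sequence energy landscape
#' (mean `tau0 * exp(E)` at each position); non-cognate crowders use a
#' flat landscape (mean `tau0` everywhere) and serve only to occupy DNA.
#'
#' Defaults are the lac repressor parameterization: 23 bp footprint,
#' specific waiting time `tau0 = 1.18e-6` s, association rate
#' `k_assoc = 2400` s^-1 and per-event unbinding probability
#' `p_unbind = 2.7e-4`, which together give a residence time
#' `t_R = tau0/p_unbind` of about 4.4 ms and a sliding length
#' `sqrt(2/p_unbind)` of about 86 bp per visit.
#'
#' @param name Species label.
#' @param copies Number of molecules (integer >= 0).
#' @param footprint Number of bp occluded when bound.
#' @param tau0 Specific waiting time between 1D events, seconds.
#' @param k_assoc Association rate per free molecule, s^-1, scaled by the
#'   fraction of start positions where the footprint fits.
#' @param p_unbind Probability that an event is a dissociation rather than
#'   a slide attempt.
#' @param cognate If `TRUE`, waiting times follow the energy landscape.
#' @return Object of class `tf_species`.
#' @export
tf_species <- function(name, copies, footprint = 23L, tau0 = 1.18e-6,
                       k_assoc = 2400, p_unbind = 2.7e-4, cognate = TRUE) {
  stopifnot(copies >= 0, footprint >= 1, tau0 > 0, k_assoc >= 0,
            p_unbind >= 0, p_unbind <= 1)
  structure(list(name = name, copies = as.integer(copies),
                 footprint = as.integer(footprint), tau0 = tau0,
                 k_assoc = k_assoc, p_unbind = p_unbind,
                 cognate = isTRUE(cognate)),
            class = "tf_species")
}

#' @export
print.tf_species <- function(x, ...) {
  cat(sprintf(
    "tf_species '%s': %d copies, footprint %d bp, tau0 %.3g s, k_assoc %.4g /s, p_unbind %.3g, %s\n",
    x$name, x$copies, x$footprint, x$tau0, x$k_assoc, x$p_unbind,
    if (x$cognate) "cognate" else "non-cognate"))
  invisible(x)
}

#' Simulation configuration
#'
#' Assembles the genome, species, energy landscape and run options into a
#' self-contained configuration. The landscape is scored once here and
#' converted into per-position mean waiting times for each cognate
#' species, so repeated simulations from the same configuration pay no
#' scoring cost.
#'
#' The recognition (motif) window of a bound cognate molecule is anchored
#' `floor((footprint - L)/2)` bp inside the footprint, centering the motif
#' in the occluded region; the target site counts as occupied only when a
#' cognate molecule's recognition window starts exactly at the annotated
#' site start (either strand).
#'
#' @param genome A `genome_seq`.
#' @param species List of `tf_species` (a single species is accepted).
#' @param pfm A `pfm`; required when any species is cognate.
#' @param target Name of the target annotation (optional).
#' @param duration Simulated seconds.
#' @param record_occupancy Record per-position occupied time (needed for
#'   occupancy profiles).
#' @param max_visit_records Store up to this many per-visit records
#'   (species, bind/unbind position, steps, dwell); 0 disables.
#' @param check_invariants Run per-event conservation and exclusion
#'   checks (slow; for testing).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(genome, species, pfm = NULL, target = NULL,
                       duration = 1, record_occupancy = FALSE,
                       max_visit_records = 0L, check_invariants = FALSE) {
  if (inherits(species, "tf_species")) species <- list(species)
  stopifnot(length(species) >= 1, duration > 0)
  M <- genome_length(genome)
  packed <- sum(vapply(species, function(s) s$copies * s$footprint,
                       numeric(1)))
  if (packed > M)
    stop("system over-packed: total footprint ", packed,
         " bp exceeds sequence length ", M, " bp")
  any_cognate <- any(vapply(species, `[[`, logical(1), "cognate"))
  landscape <- NULL
  if (any_cognate) {
    if (is.null(pfm)) stop("a pfm is required for cognate species")
    landscape <- score_landscape(genome, pfm)
  }
  cpp_species <- lapply(species, function(s) {
    li <- list(copies = s$copies, footprint = s$footprint,
               k_assoc = s$k_assoc, p_unbind = s$p_unbind, tau0 = s$tau0,
               cognate = s$cognate)
    if (s$cognate) {
      L <- landscape$L
      if (s$footprint < L)
        stop("cognate footprint (", s$footprint,
             ") must be at least the motif length (", L, ")")
      anchor <- (s$footprint - L) %/% 2L
      n_f <- M - s$footprint + 1L
      idx <- seq_len(n_f) + anchor
      li$dwell_fwd <- s$tau0 * exp(landscape$fwd[idx])
      li$dwell_rev <- s$tau0 * exp(landscape$rev[idx])
      li$anchor <- anchor
    }
    li
  })
  target_fpos <- -1L
  if (!is.null(target)) {
    hit <- genome$annotations$name == target
    if (!any(hit)) stop("target annotation '", target, "' not found")
    cog <- which(vapply(species, `[[`, logical(1), "cognate"))
    if (length(cog) == 0) stop("a cognate species is required for a target")
    anchors <- vapply(cpp_species[cog], `[[`, numeric(1), "anchor")
    fps <- vapply(species[cog], `[[`, integer(1), "footprint")
    if (length(unique(fps)) > 1)
      stop("all cognate species must share a footprint when a target is set")
    p1 <- genome$annotations$start[which(hit)[1]]
    jf1 <- p1 - anchors[1]
    if (jf1 < 1 || jf1 > M - fps[1] + 1L)
      stop("target too close to the sequence end for the footprint anchor")
    target_fpos <- as.integer(jf1 - 1L)  # 0-based for the C++ core
  }
  structure(list(genome = genome, species = species, pfm = pfm,
                 landscape = landscape, target = target,
                 target_fpos = target_fpos, duration = duration,
                 record_occupancy = record_occupancy,
                 max_visit_records = as.integer(max_visit_records),
                 check_invariants = check_invariants,
                 cpp_species = cpp_species, M = M),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$M, "bp,", length(x$species), "species,",
      x$duration, "s", if (!is.null(x$target)) paste0("target '", x$target, "'"),
      "\n")
  for (s in x$species) print(s)
  invisible(x)
}

#' Run one facilitated-diffusion simulation
#'
#' Event-driven kinetic Monte Carlo: free molecules associate at rate
#' `k_assoc * n_free * A_free/A_total` landing uniformly on free start
#' positions; bound molecules draw exponential waiting times (mean
#' `tau0 * exp(E)` for cognate species) and at each event either unbind
#' with probability `p_unbind` or attempt a 1 bp slide left/right with
#' equal probability, rejected if blocked by another footprint or a
#' sequence end. All molecules start free at `t = 0`.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; combined with `rep` to define the RNG stream.
#' @param rep Replicate index (distinct values give independent streams).
#' @return Object of class `sim_trajectory`: per-species summary
#'   `$species` (visits, steps, dwell, integrated bound time), `$fpt`
#'   (first-passage time to the target, `NA` if never reached = censored),
#'   `$target_time`, per-position occupied time `$occupancy` (if
#'   recorded; indexed by footprint start), visit records `$visits`,
#'   `$n_events`, `$duration`.
#' @export
simulate_fd <- function(config, seed = 1L, rep = 0L) {
  res <- fd_simulate_cpp(
    M = config$M, species = config$cpp_species,
    duration = config$duration, target_fpos = config$target_fpos,
    seed_hi = as.double(seed), seed_lo = as.double(rep),
    record_occupancy = config$record_occupancy,
    max_visit_records = config$max_visit_records,
    check_invariants = config$check_invariants)
  if (res$violations > 0)
    warning("invariant violations detected: ", res$violations)
  nm <- vapply(config$species, `[[`, character(1), "name")
  stats <- as.data.frame(res$species_stats)
  stats <- cbind(data.frame(name = nm,
                            footprint = vapply(config$species, `[[`,
                                               integer(1), "footprint"),
                            cognate = vapply(config$species, `[[`,
                                             logical(1), "cognate")),
                 stats)
  visits <- as.data.frame(res$visits)
  if (nrow(visits) > 0) visits$species <- nm[visits$species]
  occupancy <- NULL
  if (config$record_occupancy) {
    occupancy <- res$occupancy
    names(occupancy) <- nm
  }
  structure(list(species = stats, fpt = res$fpt,
                 target_time = res$target_time,
                 duration = config$duration, occupancy = occupancy,
                 visits = visits, n_events = res$n_events,
                 M = config$M, target_fpos = config$target_fpos,
                 seed = seed, rep = rep,
                 violations = res$violations),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("sim_trajectory: %.3g s on %d bp, %.3g events\n",
              x$duration, x$M, x$n_events))
  print(x$species)
  if (!is.na(x$fpt) || x$target_fpos >= 0)
    cat(sprintf("  first passage to target: %s s; target occupied %.3g s\n",
                ifelse(is.na(x$fpt), "censored", format(x$fpt, digits = 4)),
                x$target_time))
  invisible(x)
}

#' Run independent replicate simulations
#'
#' Each replicate uses an RNG stream derived deterministically from
#' `(base_seed, replicate index)`, so the full set is reproducible and
#' replicates are independent.
#'
#' @param config A `sim_config`.
#' @param n_reps Number of replicates.
#' @param base_seed Integer seed.
#' @param summarize Optional function applied to each trajectory; when
#'   given, its value is stored instead of the full trajectory (keeps
#'   memory flat for large designs).
#' @return List of `sim_trajectory` (or of `summarize` results).
#' @export
run_replicates <- function(config, n_reps, base_seed = 1L,
                           summarize = NULL) {
  stopifnot(n_reps >= 1)
  lapply(seq_len(n_reps), function(i) {
    traj <- simulate_fd(config, seed = base_seed, rep = i)
    if (is.null(summarize)) traj else summarize(traj)
  })
}
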