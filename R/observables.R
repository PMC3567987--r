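#' Per-bp coverage from a trajectory
#'
#' Converts the recorded per-footprint-start occupied times into the
#' fraction of simulated time each bp was covered by a molecule of the
#' selected species (a bound molecule at start `j` covers
#' `[j, j + footprint)`).
#'
#' @param traj A `sim_trajectory` recorded with `record_occupancy = TRUE`.
#' @param species Character vector of species names; default: all cognate
#'   species.
#' @param window `c(start, end)` 1-based inclusive bp interval; default
#'   the whole sequence.
#' @return Numeric vector of per-bp covered-time fractions (in [0, 1]).
#' @export
coverage_profile <- function(traj, species = NULL, window = NULL) {
  if (is.null(traj$occupancy))
    stop("trajectory was not recorded with record_occupancy = TRUE")
  st <- traj$species
  if (is.null(species)) species <- st$name[st$cognate]
  if (length(species) == 0) stop("no species selected")
  M <- traj$M
  cov <- numeric(M)
  b <- seq_len(M)
  for (nm in species) {
    row <- which(st$name == nm)[1]
    if (is.na(row)) stop("species '", nm, "' not in trajectory")
    acc <- traj$occupancy[[nm]]
    w <- st$footprint[row]
    n <- length(acc)
    cs <- c(0, cumsum(acc))
    hi <- pmin(b, n)
    lo <- pmax(b - w, 0L)
    cov <- cov + (cs[hi + 1L] - cs[lo + 1L])
  }
  cov <- cov / traj$duration
  if (!is.null(window)) cov <- cov[window[1]:window[2]]
  cov
}

#' Occupancy-bias profile
#'
#' The occupancy bias is the per-bp covered-time fraction divided by its
#' mean over the window, making profiles scale-free and comparable
#' between systems of different size and abundance. A window with zero
#' total coverage is returned un-normalized and flagged.
#'
#' @param traj A `sim_trajectory` (with occupancy recorded), or a numeric
#'   coverage vector as from [coverage_profile()].
#' @param window `c(start, end)` 1-based bp interval (applied when `traj`
#'   is a trajectory).
#' @param species Species selection passed to [coverage_profile()].
#' @return Object of class `occupancy_profile`: list with `bias`, `raw`,
#'   `window`, `normalized`.
#' @export
occupancy_bias <- function(traj, window = NULL, species = NULL) {
  raw <- if (is.numeric(traj)) traj else
    coverage_profile(traj, species = species, window = window)
  m <- mean(raw)
  normalized <- m > 0
  structure(list(bias = if (normalized) raw / m else raw, raw = raw,
                 window = window, normalized = normalized),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat("occupancy_profile:", length(x$bias), "bp,",
      if (x$normalized) "mean-normalized" else "raw (zero coverage)", "\n")
  invisible(x)
}

#' Mean occupancy-bias profile over replicates
#'
#' @param profiles List of `occupancy_profile` on a common window.
#' @return Numeric vector: the per-bp mean of the bias profiles.
#' @export
mean_bias_profile <- function(profiles) {
  mat <- vapply(profiles, function(p) p$bias,
                numeric(length(profiles[[1]]$bias)))
  rowMeans(mat)
}

#' Pearson correlation of occupancy-bias profiles to a reference
#'
#' One coefficient per replicate profile; profiles with zero variance
#' give `NA`.
#'
#' @param profiles List of `occupancy_profile` (or numeric vectors).
#' @param reference Numeric reference profile (e.g. the mean full-system
#'   bias from [mean_bias_profile()]).
#' @return Numeric vector of Pearson r.
#' @export
occupancy_correlation <- function(profiles, reference) {
  vapply(profiles, function(p) {
    v <- if (is.numeric(p)) p else p$bias
    if (sd(v) == 0 || sd(reference) == 0) return(NA_real_)
    cor(v, reference)
  }, numeric(1))
}

#' Normalized affinity / normalized occupancy per strong site
#'
#' Selects the strong sites of the landscape: positions (on either
#' strand) whose score is within `threshold_frac` of the full score range
#' below the maximum, i.e. `E >= E_max - threshold_frac*(E_max - E_min)`.
#' For that set, the affinity `a ~ exp(E)` and the occupancy `o` (covered
#' time at the site's motif-start bp) are each normalized to sum to 1,
#' and their ratio `a/o` reported per site. At thermodynamic equilibrium
#' and low copy number the ratios approach 1; under crowding the
#' occupancy flattens relative to affinity, pushing weak-site ratios
#' below 1 (false positives).
#'
#' @param coverage Per-bp raw coverage vector ([coverage_profile()]),
#'   aligned with the landscape's sequence.
#' @param landscape An `energy_landscape` of the same sequence.
#' @param threshold_frac Fraction of the score range defining "strong"
#'   (default 0.3).
#' @param window Optional `c(start, end)` restriction (1-based, on motif
#'   start positions).
#' @return `data.frame` with columns `position`, `strand`, `score`,
#'   `affinity`, `occupancy`, `ratio`.
#' @export
affinity_occupancy_ratio <- function(coverage, landscape,
                                     threshold_frac = 0.3, window = NULL) {
  n <- length(landscape$fwd)
  E <- c(landscape$fwd, landscape$rev)
  pos <- rep(seq_len(n), 2L)
  strand <- rep(c("+", "-"), each = n)
  if (!is.null(window)) {
    keep <- pos >= window[1] & pos <= window[2]
    E <- E[keep]; pos <- pos[keep]; strand <- strand[keep]
  }
  cut <- max(E) - threshold_frac * (max(E) - min(E))
  sel <- E >= cut
  if (!any(sel)) stop("invalid-threshold: empty site set")
  E <- E[sel]; pos <- pos[sel]; strand <- strand[sel]
  a <- exp(E) / sum(exp(E))
  o_raw <- coverage[pos]
  o <- if (sum(o_raw) > 0) o_raw / sum(o_raw) else o_raw
  data.frame(position = pos, strand = strand, score = E, affinity = a,
             occupancy = o, ratio = ifelse(o > 0, a / o, NA_real_))
}

#' First-passage time to the target
#'
#' @param traj A `sim_trajectory` simulated with a target.
#' @return List with `time` (seconds; the duration if censored) and
#'   `censored` (`TRUE` when the target was never reached).
#' @export
first_passage_time <- function(traj) {
  if (traj$target_fpos < 0) stop("trajectory has no target")
  if (is.na(traj$fpt)) list(time = traj$duration, censored = TRUE)
  else list(time = traj$fpt, censored = FALSE)
}

#' Probability that the target site is occupied
#'
#' The fraction of simulated time during which a cognate molecule's
#' recognition window start coincided with the target site start. For
#' long runs this approximates the stationary occupancy probability.
#'
#' @param traj A `sim_trajectory` simulated with a target.
#' @return Fraction in [0, 1].
#' @export
target_occupancy_probability <- function(traj) {
  if (traj$target_fpos < 0) stop("trajectory has no target")
  traj$target_time / traj$duration
}

#' One-dimensional random-walk statistics
#'
#' Per-visit statistics of a species, pooled over one or more
#' trajectories. The residence time `t_R` is the renewal (ratio)
#' estimator: total bound molecule-time divided by the number of binding
#' events (completed visits plus visits still open at the horizon). This
#' keeps `t_R` consistent with the bound-fraction bookkeeping and with
#' the association-rate inversion `k = (1/t_R) f/(1-f) (A/A_tot)`, and
#' avoids the downward bias of discarding long visits cut off by the end
#' of the run. The step count `N` and the observed sliding length
#' `sl_obs = sqrt(2 N)` bp are averaged over completed visits.
#'
#' @param trajectories A `sim_trajectory` or list of them.
#' @param species Species name (default: first cognate).
#' @return List with `t_R` (s), `t_R_completed` (mean dwell over
#'   completed visits only), `n_steps`, `sl_obs` (bp), `f`, `n_visits`
#'   (completed), `n_open` (censored).
#' @export
one_dim_stats <- function(trajectories, species = NULL) {
  if (inherits(trajectories, "sim_trajectory"))
    trajectories <- list(trajectories)
  tot <- c(visits = 0, steps = 0, dwell = 0, bound = 0, moltime = 0,
           open = 0)
  for (tr in trajectories) {
    st <- tr$species
    row <- if (is.null(species)) {
      if (any(st$cognate)) which(st$cognate)[1] else 1L
    } else which(st$name == species)[1]
    if (is.na(row)) stop("species not found in trajectory")
    tot <- tot + c(st$n_visits[row], st$sum_steps[row], st$sum_dwell[row],
                   st$bound_time[row], st$copies[row] * tr$duration,
                   st$open_visits[row])
  }
  f <- if (tot[["moltime"]] > 0) tot[["bound"]] / tot[["moltime"]] else
    NA_real_
  started <- tot[["visits"]] + tot[["open"]]
  if (tot[["visits"]] == 0) {
    return(list(t_R = if (started > 0) tot[["bound"]] / started else
                  NA_real_,
                t_R_completed = NA_real_, n_steps = NA_real_,
                sl_obs = NA_real_, f = f, n_visits = 0,
                n_open = tot[["open"]]))
  }
  nbar <- tot[["steps"]] / tot[["visits"]]
  list(t_R = tot[["bound"]] / started,
       t_R_completed = tot[["dwell"]] / tot[["visits"]], n_steps = nbar,
       sl_obs = sqrt(2 * nbar), f = f, n_visits = tot[["visits"]],
       n_open = tot[["open"]])
}

#' Write a coverage or bias profile as bedGraph (0-based half-open)
#'
#' @param values Per-bp numeric vector.
#' @param path Output path.
#' @param chrom Chromosome/sequence label.
#' @param offset 0-based offset of the first value.
#' @export
write_bedgraph <- function(values, path, chrom = "genome", offset = 0L) {
  # run-length encode constant stretches
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  df <- data.frame(chrom = chrom, start = starts + offset,
                   end = ends + offset, value = r$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
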