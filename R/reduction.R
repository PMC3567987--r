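#' Model I: copy-number scaling
#'
#' To keep the number of bound molecules per bp (local crowding) equal
#' between a full system and a subsystem of relative size `lambda`, the
#' copy-number model scales the molecule count as
#' `TF_lambda = round(lambda * TF)` (round half to even). Because copy
#' numbers are integers, the reduction is infeasible when the rounded
#' value drops below 1.
#'
#' @param tf_full Copy number in the full system (integer >= 1).
#' @param lambda Subsystem-to-full length ratio, in (0, 1].
#' @return List with `copies` (scaled integer), `lambda`, `feasible`.
#' @export
scale_copy_number <- function(tf_full, lambda) {
  stopifnot(tf_full >= 1)
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  n <- as.integer(round(lambda * tf_full))  # round() is half-to-even
  list(copies = n, lambda = lambda, feasible = n >= 1L)
}

#' Model II: association-rate scaling
#'
#' Keeps the copy number fixed and rescales the association rate so that
#' the subsystem's bound-molecule density matches the full system. If a
#' molecule spends a fraction `f` of its time bound in the full system,
#' the subsystem bound fraction must be `lambda * f`, which is achieved
#' by scaling the association rate by
#' \deqn{\gamma = \lambda(1-f) / (1 - \lambda f)}
#'
#' @param k_assoc Full-system association rate, s^-1.
#' @param lambda Subsystem-to-full length ratio, in (0, 1].
#' @param f Fraction of time a molecule spends bound in the full system,
#'   in [0, 1).
#' @return List with `gamma`, `k_lambda` (= `gamma * k_assoc`) and
#'   `bound_fraction_sub` (= `lambda * f`).
#' @export
scale_assoc_rate <- function(k_assoc, lambda, f) {
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  if (f < 0 || f >= 1) stop("f must be in [0, 1)")
  gamma <- lambda * (1 - f) / (1 - lambda * f)
  list(gamma = gamma, k_lambda = gamma * k_assoc,
       bound_fraction_sub = lambda * f)
}

#' Estimate the association rate from 1D statistics
#'
#' Inverts the steady-state balance `TF_bound/TF_free = f/(1-f)`:
#' `k_assoc = (1/t_R) * f/(1-f) * (A_max/A_total)`, with `A_max/A_total`
#' the free-DNA ratio.
#'
#' @param t_R Residence time per visit, seconds.
#' @param f Bound-time fraction, in [0, 1).
#' @param free_dna_ratio Ratio of free DNA (default 1).
#' @return Association rate in s^-1.
#' @export
estimate_assoc_rate <- function(t_R, f, free_dna_ratio = 1) {
  stopifnot(t_R > 0, free_dna_ratio > 0, free_dna_ratio <= 1)
  if (f < 0 || f >= 1) stop("f must be in [0, 1)")
  (1 / t_R) * (f / (1 - f)) * free_dna_ratio
}

#' Measure the bound-time fraction from simulations
#'
#' Pools the integrated bound molecule-time over replicates:
#' `f = sum(bound time) / sum(copies * duration)`. The standard error is
#' taken across replicate-level `f` values.
#'
#' @param trajectories A `sim_trajectory` or list of them.
#' @param species Species name (default: first cognate species).
#' @return List with `f`, `se` (NA for a single replicate), `n_reps`.
#' @export
estimate_f <- function(trajectories, species = NULL) {
  if (inherits(trajectories, "sim_trajectory"))
    trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  per_rep <- vapply(trajectories, function(tr) {
    st <- tr$species
    row <- if (is.null(species)) {
      if (any(st$cognate)) which(st$cognate)[1] else 1L
    } else which(st$name == species)[1]
    if (is.na(row)) stop("species not found in trajectory")
    tot <- st$copies[row] * tr$duration
    if (tot <= 0) stop("zero total molecule-time")
    st$bound_time[row] / tot
  }, numeric(1))
  weights <- vapply(trajectories, function(tr) {
    st <- tr$species
    row <- if (is.null(species)) {
      if (any(st$cognate)) which(st$cognate)[1] else 1L
    } else which(st$name == species)[1]
    st$copies[row] * tr$duration
  }, numeric(1))
  f <- sum(per_rep * weights) / sum(weights)
  se <- if (length(per_rep) > 1) sd(per_rep) / sqrt(length(per_rep)) else NA_real_
  list(f = f, se = se, n_reps = length(per_rep))
}

#' Smallest subsystem for which copy-number scaling is feasible
#'
#' @param tf_full Full-system copy number.
#' @param sizes Candidate subsystem sizes in bp (any order).
#' @param lambdas Matching length ratios.
#' @return The smallest feasible size (bp).
#' @export
min_feasible_subsystem <- function(tf_full, sizes, lambdas) {
  stopifnot(length(sizes) == length(lambdas))
  ord <- order(sizes)
  for (i in ord) {
    if (scale_copy_number(tf_full, lambdas[i])$feasible) return(sizes[i])
  }
  stop("infeasible-subsystem: no candidate size admits at least one molecule")
}

#' Length ratio from total waiting times
#'
#' Alternative definition of the scaling factor: the ratio between the
#' sum of mean waiting times `tau0 * exp(E)` over all positions and both
#' strands in the subsystem and the same sum in the full system. On
#' background-like sequence (`<exp E> = 1`) this reduces to the length
#' ratio.
#'
#' @param full Full-system `energy_landscape`.
#' @param sub Subsystem `energy_landscape`.
#' @param tau0 Specific waiting time (cancels in the ratio; kept for
#'   dimensional clarity).
#' @return The waiting-time scaling factor.
#' @export
lambda_from_waiting_times <- function(full, sub, tau0 = 1.18e-6) {
  if (length(full$fwd) == 0 || length(sub$fwd) == 0)
    stop("empty landscape")
  num <- sum(tau0 * exp(sub$fwd)) + sum(tau0 * exp(sub$rev))
  den <- sum(tau0 * exp(full$fwd)) + sum(tau0 * exp(full$rev))
  num / den
}

#' Build a subsystem reduction plan
#'
#' Combines the two scaling models into a report: Model I (copy-number)
#' scales molecule counts by `lambda`; Model II (association-rate) keeps
#' the counts and scales the association rate by
#' `gamma = lambda(1-f)/(1-lambda f)`.
#'
#' @param lambda Length ratio, computed from actual constructed lengths.
#' @param model `"copy_number"` or `"assoc_rate"`.
#' @param tf_full Full-system copy number of the species of interest.
#' @param k_assoc_full Full-system association rate, s^-1.
#' @param f Bound-time fraction in the full system (required for
#'   Model II).
#' @return Object of class `reduction_plan`.
#' @export
reduction_plan <- function(lambda, model = c("copy_number", "assoc_rate"),
                           tf_full, k_assoc_full, f = NA_real_) {
  model <- match.arg(model)
  plan <- list(lambda = lambda, model = model, f = f, tf_full = tf_full,
               tf_lambda = NA_integer_, gamma = NA_real_,
               k_assoc_full = k_assoc_full, k_assoc_lambda = NA_real_,
               feasible = TRUE)
  if (model == "copy_number") {
    sc <- scale_copy_number(tf_full, lambda)
    plan$tf_lambda <- sc$copies
    plan$k_assoc_lambda <- k_assoc_full
    plan$feasible <- sc$feasible
  } else {
    if (is.na(f)) stop("Model II requires the bound-time fraction f")
    sc <- scale_assoc_rate(k_assoc_full, lambda, f)
    plan$tf_lambda <- as.integer(tf_full)
    plan$gamma <- sc$gamma
    plan$k_assoc_lambda <- sc$k_lambda
  }
  class(plan) <- "reduction_plan"
  plan
}

#' @export
print.reduction_plan <- function(x, ...) {
  cat("reduction_plan (", x$model, "): lambda = ", signif(x$lambda, 4),
      "\n", sep = "")
  if (x$model == "copy_number") {
    cat("  copies: ", x$tf_full, " -> ",
        if (x$feasible) x$tf_lambda else "infeasible (< 1 molecule)", "\n",
        sep = "")
  } else {
    cat(sprintf("  f = %.4g, gamma = %.6g, k_assoc: %.4g -> %.4g /s\n",
                x$f, x$gamma, x$k_assoc_full, x$k_assoc_lambda))
  }
  invisible(x)
}

#' Apply a reduction model to a species list
#'
#' Model I multiplies every species' copy number by `lambda` (rounding
#' half to even); Model II multiplies every species' association rate by
#' `gamma(lambda, f)`, leaving copy numbers unchanged.
#'
#' @param species List of `tf_species`.
#' @param lambda Length ratio.
#' @param model `"copy_number"` or `"assoc_rate"`.
#' @param f Full-system bound-time fraction (Model II only). Either a
#'   single value or a named vector with one entry per species.
#' @return List of adjusted `tf_species`.
#' @export
reduce_species <- function(species, lambda,
                           model = c("copy_number", "assoc_rate"),
                           f = NA_real_) {
  model <- match.arg(model)
  if (inherits(species, "tf_species")) species <- list(species)
  lapply(species, function(s) {
    if (model == "copy_number") {
      sc <- scale_copy_number(s$copies, lambda)
      if (!sc$feasible)
        stop("infeasible copy-number reduction for species '", s$name,
             "' (", s$copies, " x ", lambda, " rounds below 1); ",
             "use the association-rate model")
      s$copies <- sc$copies
    } else {
      fs <- if (length(f) > 1) f[[s$name]] else f
      if (is.na(fs)) stop("Model II requires f for species '", s$name, "'")
      s$k_assoc <- scale_assoc_rate(s$k_assoc, lambda, fs)$k_lambda
    }
    s
  })
}
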