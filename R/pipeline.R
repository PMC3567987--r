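#' Read an experiment configuration
#'
#' YAML (or JSON) with the schema:
#' \preformatted{
#' genome:
#'   fasta: path/to.fa        # or:
#'   synth: {length: 46000, seed: 1}
#'   plant:                   # optional
#'     - {name: O1, operator: O1, position: 23000}
#'     - {name: site, seq: ACGT..., position: 100}
#' species:
#'   - {name: lacI, copies: 10, cognate: true}    # kinetic fields optional
#'   - {name: crowder, copies: 500, cognate: false}
#' target: O1                 # optional
#' duration: 2                # seconds
#' replicates: 10
#' reduce:                    # optional
#'   model: copy_number       # or assoc_rate
#'   lambda: 0.01
#'   f: 0.88                  # assoc_rate only
#' }
#' Units: bp (positions, lengths), seconds (duration, tau0), s^-1
#' (k_assoc); probabilities dimensionless.
#'
#' @param path Config file path.
#' @return Named list (validated).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = FALSE)
  else yaml::read_yaml(path)
  for (key in c("genome", "species", "duration")) {
    if (is.null(cfg[[key]]))
      stop("config error: missing key '", key, "'")
  }
  for (i in seq_along(cfg$species)) {
    s <- cfg$species[[i]]
    for (key in c("name", "copies")) {
      if (is.null(s[[key]]))
        stop("config error: species[", i, "] missing key '", key, "'")
    }
  }
  cfg
}

.build_genome <- function(gc, seed) {
  g <- if (!is.null(gc$fasta)) {
    read_fasta(gc$fasta)
  } else if (!is.null(gc$synth)) {
    if (is.null(gc$synth$length))
      stop("config error: genome.synth missing key 'length'")
    synthesize_genome(gc$synth$length,
                      seed = if (!is.null(gc$synth$seed)) gc$synth$seed
                      else seed)
  } else stop("config error: genome needs 'fasta' or 'synth'")
  for (p in gc$plant) {
    sq <- if (!is.null(p$operator)) lacI_sites(FALSE)[[p$operator]] else p$seq
    if (is.null(sq) || is.null(p$position) || is.null(p$name))
      stop("config error: plant entries need name, position and seq/operator")
    g <- plant_site(g, sq, p$position, p$name)
  }
  g
}

.build_species <- function(sc) {
  lapply(sc, function(s) {
    tf_species(s$name, s$copies,
               footprint = s$footprint %||% 23L,
               tau0 = s$tau0 %||% 1.18e-6,
               k_assoc = s$k_assoc %||% 2400,
               p_unbind = s$p_unbind %||% 2.7e-4,
               cognate = s$cognate %||% TRUE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment end to end
#'
#' Builds the PWM (lac operators unless `sites` given in the config),
#' builds or reads the genome, optionally applies a reduction model to
#' the species, simulates the requested replicates and writes per-
#' replicate summary TSVs plus a JSON manifest (config snapshot, seeds,
#' package version, output paths). Re-running with the same config and
#' seed reproduces all outputs byte for byte.
#'
#' @param config_path Path to a YAML/JSON config (see [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer base seed.
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(config_path, out_dir, seed = 1L) {
  cfg <- read_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[fdsim] ", sprintf(...))

  log_stage("stage build-pwm")
  sites <- if (!is.null(cfg$sites)) read_sites(cfg$sites) else lacI_sites()
  pfm <- build_pfm(sites, zeta = cfg$zeta %||% 1)

  log_stage("stage genome")
  genome <- .build_genome(cfg$genome, seed)
  species <- .build_species(cfg$species)

  red <- NULL
  if (!is.null(cfg$reduce)) {
    lam <- cfg$reduce$lambda
    if (is.null(lam) || is.null(cfg$reduce$model))
      stop("config error: reduce needs 'model' and 'lambda'")
    log_stage("stage reduce: model %s, lambda %.4g", cfg$reduce$model, lam)
    if (cfg$reduce$model == "copy_number") {
      infeas <- vapply(species, function(s)
        !scale_copy_number(s$copies, lam)$feasible, logical(1))
      if (any(infeas)) {
        warning("infeasible copy-number reduction for ",
                paste(vapply(species[infeas], `[[`, character(1), "name"),
                      collapse = ", "),
                "; consider the association-rate model",
                call. = FALSE)
        stop("infeasible-reduction")
      }
    }
    k_full <- species[[1]]$k_assoc
    species <- reduce_species(species, lam, cfg$reduce$model,
                              f = cfg$reduce$f %||% NA_real_)
    red <- reduction_plan(lam, cfg$reduce$model,
                          tf_full = cfg$species[[1]]$copies,
                          k_assoc_full = k_full,
                          f = cfg$reduce$f %||% NA_real_)
  }

  n_reps <- cfg$replicates %||% 1L
  any_cognate <- any(vapply(species, `[[`, logical(1), "cognate"))
  sim_cfg <- sim_config(genome, species, pfm = if (any_cognate) pfm,
                        target = cfg$target,
                        duration = cfg$duration,
                        record_occupancy = isTRUE(cfg$record_occupancy))
  log_stage("stage simulate: %d replicate(s), %g s each", n_reps,
            cfg$duration)
  trs <- run_replicates(sim_cfg, n_reps, base_seed = seed)

  log_stage("stage analyze")
  summary_df <- do.call(rbind, lapply(seq_along(trs), function(i) {
    tr <- trs[[i]]
    st <- one_dim_stats(tr)
    data.frame(rep = i, seed = seed,
               f = st$f, t_R = st$t_R, sl_obs = st$sl_obs,
               n_visits = st$n_visits,
               fpt = if (tr$target_fpos >= 0)
                 first_passage_time(tr)$time else NA_real_,
               fpt_censored = if (tr$target_fpos >= 0)
                 first_passage_time(tr)$censored else NA,
               p_occ = if (tr$target_fpos >= 0)
                 target_occupancy_probability(tr) else NA_real_,
               n_events = tr$n_events)
  }))
  summary_path <- file.path(out_dir, "replicates.tsv")
  write.table(summary_df, summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  pwm_path <- file.path(out_dir, "pwm.tsv")
  write_pfm(pfm, pwm_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fdsim")),
    config = cfg, base_seed = seed,
    replicate_seeds = lapply(seq_len(n_reps), function(i)
      c(seed = seed, rep = i)),
    genome_length = genome_length(genome),
    outputs = list(replicates = summary_path, pwm = pwm_path),
    reduction = if (!is.null(red)) unclass(red),
    timestamp = format(Sys.time(), tz = "UTC"))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  log_stage("done: %s", out_dir)
  invisible(manifest)
}
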