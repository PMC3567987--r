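#' Genome sequence container
#'
#' A linear DNA sequence with named site annotations. Coordinates are
#' 1-based closed intervals inside R; file exports (BED) use 0-based
#' half-open coordinates.
#'
#' @param seq DNA string over A/C/G/T.
#' @param name Sequence label.
#' @param annotations `data.frame` with columns `name`, `start`, `end`,
#'   `strand` (1-based, end inclusive).
#' @return Object of class `genome_seq`.
#' @export
genome_seq <- function(seq, name = "genome",
                       annotations = .empty_annotations()) {
  seq <- toupper(seq)
  code <- .seq_to_code(seq)
  if (anyNA(code))
    stop("sequence contains non-ACGT character at position ",
         which(is.na(code))[1])
  M <- nchar(seq)
  if (nrow(annotations) > 0) {
    bad <- annotations$start < 1 | annotations$end > M |
      annotations$end < annotations$start
    if (any(bad))
      stop("annotation out of range: ", annotations$name[which(bad)[1]])
  }
  structure(list(seq = seq, name = name, annotations = annotations),
            class = "genome_seq")
}

.empty_annotations <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq '", x$name, "': ", nchar(x$seq), " bp, ",
      nrow(x$annotations), " annotation(s)\n", sep = "")
  if (nrow(x$annotations) > 0) print(x$annotations)
  invisible(x)
}

#' Genome length
#' @param genome A `genome_seq`.
#' @return Length in bp.
#' @export
genome_length <- function(genome) nchar(genome$seq)

#' Generate an i.i.d. random genome with a prescribed base composition
#'
#' Draws each position independently from the background distribution.
#' Used as a stand-in for a real genome when only the base composition
#' matters; reproducible for a given seed.
#'
#' @param length Sequence length in bp.
#' @param bg An `nt_background`.
#' @param seed Integer seed (optional; uses the current RNG state if `NULL`).
#' @param name Sequence label.
#' @return A `genome_seq`.
#' @export
synthesize_genome <- function(length, bg = ecoli_background(), seed = NULL,
                              name = "synthetic") {
  stopifnot(length > 0)
  draw <- function() {
    paste(sample(NUCS, length, replace = TRUE, prob = as.numeric(bg)),
          collapse = "")
  }
  seq <- if (is.null(seed)) draw() else withr_with_seed(seed, draw())
  genome_seq(seq, name = name)
}

# Minimal local seed scoping (avoids perturbing the caller's RNG stream).
withr_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Plant a site sequence into a genome
#'
#' Replaces the window starting at `position` with `site_seq` and records
#' an annotation under `name`.
#'
#' @param genome A `genome_seq`.
#' @param site_seq DNA string to insert (replaces, does not shift).
#' @param position 1-based start of the replaced window.
#' @param name Annotation name.
#' @param strand Annotation strand (default `"+"`).
#' @return Modified `genome_seq`.
#' @export
plant_site <- function(genome, site_seq, position, name, strand = "+") {
  site_seq <- toupper(site_seq)
  w <- nchar(site_seq)
  M <- genome_length(genome)
  if (position < 1 || position + w - 1L > M)
    stop("planted site [", position, ", ", position + w - 1L,
         "] does not fit in sequence of length ", M)
  seq <- paste0(substr(genome$seq, 1L, position - 1L), site_seq,
                substr(genome$seq, position + w, M))
  ann <- rbind(genome$annotations,
               data.frame(name = name, start = position,
                          end = position + w - 1L, strand = strand,
                          stringsAsFactors = FALSE))
  genome_seq(seq, name = genome$name, annotations = ann)
}

#' Extract a subsystem window around a target site
#'
#' Returns a contiguous window of exactly `size` bp containing the target
#' annotation with at least `margin_min` bp between the target and either
#' window end. The window is placed so the target is as central as the
#' full sequence allows (a target near one end of the full sequence pushes
#' the window against that end). Annotations falling fully inside the
#' window are re-mapped to window coordinates; others are dropped.
#'
#' @param genome A `genome_seq` with the target annotated.
#' @param target Name of the target annotation.
#' @param size Window size in bp.
#' @param margin_min Minimum distance (bp) from each target edge to the
#'   window ends; defaults to 10% of `size`.
#' @return A `genome_seq` of length `size` with attribute `lambda`
#'   (= `size` / full length) and attribute `offset` (1-based start of the
#'   window in the full sequence).
#' @export
extract_subsystem <- function(genome, target, size,
                              margin_min = round(0.1 * size)) {
  M <- genome_length(genome)
  if (size > M) stop("subsystem size exceeds genome length")
  ann <- genome$annotations
  hit <- ann$name == target
  if (!any(hit)) stop("target annotation '", target, "' not found")
  tgt <- ann[which(hit)[1], ]
  site_len <- tgt$end - tgt$start + 1L
  if (size < 2 * margin_min + site_len)
    stop("infeasible subsystem: size ", size, " cannot hold the ",
         site_len, " bp target with ", margin_min, " bp margins")
  # center the target, clamp to the sequence
  mid <- (tgt$start + tgt$end) / 2
  start <- round(mid - size / 2 + 0.5)
  start <- max(1L, min(as.integer(start), M - as.integer(size) + 1L))
  end <- start + as.integer(size) - 1L
  if (tgt$start - start < margin_min || end - tgt$end < margin_min)
    stop("infeasible subsystem: margins of ", margin_min,
         " bp around the target cannot be satisfied")
  keep <- ann$start >= start & ann$end <= end
  new_ann <- ann[keep, , drop = FALSE]
  new_ann$start <- new_ann$start - start + 1L
  new_ann$end <- new_ann$end - start + 1L
  rownames(new_ann) <- NULL
  out <- genome_seq(substr(genome$seq, start, end),
                    name = paste0(genome$name, ":", start, "-", end),
                    annotations = new_ann)
  attr(out, "lambda") <- size / M
  attr(out, "offset") <- start
  out
}

#' Read a genome from FASTA
#'
#' Reads the first record, uppercases it, and rejects ambiguity codes.
#' @param path FASTA path.
#' @return A `genome_seq`.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  genome_seq(as.character(ss[[1]]), name = names(ss)[1])
}

#' Write a genome to FASTA
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write annotations as BED (0-based half-open)
#' @param genome A `genome_seq`.
#' @param path Output path.
#' @export
write_bed <- function(genome, path) {
  ann <- genome$annotations
  df <- data.frame(chrom = genome$name, start = ann$start - 1L,
                   end = ann$end, name = ann$name, score = 0L,
                   strand = ann$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
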