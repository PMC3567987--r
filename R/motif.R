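#' @useDynLib fdsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd cor var aggregate
#' @importFrom utils write.table read.table
NULL

NUCS <- c("A", "C", "G", "T")

# Map an ACGT string to integer codes 1..4; anything else becomes NA.
.seq_to_code <- function(seq) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[as.integer(charToRaw(seq))]
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Background nucleotide composition
#'
#' Genomic background frequencies used both to generate synthetic sequence
#' and as the reference distribution in motif scoring. The default is the
#' E. coli K-12 composition.
#'
#' @param A,C,G,T Nucleotide frequencies; must be positive and sum to 1.
#' @return Named numeric vector of class `nt_background`.
#' @export
nt_background <- function(A = 0.246, C = 0.254, G = 0.254, T = 0.246) {
  bg <- c(A = A, C = C, G = G, T = T)
  if (any(bg <= 0)) stop("all background frequencies must be > 0")
  if (abs(sum(bg) - 1) > 1e-9) stop("background frequencies must sum to 1")
  class(bg) <- "nt_background"
  bg
}

#' E. coli K-12 background composition
#' @return An `nt_background` with the E. coli K-12 frequencies
#'   (A = T = 0.246, C = G = 0.254).
#' @export
ecoli_background <- function() nt_background()

#' Lac repressor high-affinity binding sites
#'
#' The three known high-affinity lac operator sequences (O1, O2, O3). The
#' lacI tetramer is built from two dimers each reading only 6 bp, so for
#' motif construction the middle 9 bp are masked as a gap (`N`).
#'
#' @param gapped If `TRUE` (default) return the gap-masked sequences used to
#'   build the position frequency matrix; otherwise the full 21-bp sites.
#' @return Named character vector of the three sites.
#' @export
lacI_sites <- function(gapped = TRUE) {
  full <- c(
    O1 = "AATTGTGAGCGGATAACAATT",
    O2 = "AAATGTGAGCGAGTAACAACC",
    O3 = "GGCAGTGAGCGCAACGCAATT"
  )
  if (!gapped) return(full)
  vapply(full, function(s) {
    paste0(substr(s, 1L, 6L), strrep("N", 9L), substr(s, 16L, 21L))
  }, character(1), USE.NAMES = TRUE)
}

#' Aligned binding-site set
#'
#' Validates a set of aligned, equal-length binding-site sequences over
#' `{A,C,G,T,N}`. `N` marks gap columns, which must be identical across all
#' sites (the motif model treats them as uninformative).
#'
#' @param sites Character vector of aligned site sequences.
#' @return Character vector of class `binding_site_set`.
#' @export
binding_sites <- function(sites) {
  sites <- toupper(as.character(sites))
  if (length(sites) == 0L) stop("at least one site sequence is required")
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L)
    stop("all binding sites must have identical length; got lengths ",
         paste(unique(lens), collapse = ", "))
  chars <- strsplit(sites, "", fixed = TRUE)
  ok <- vapply(chars, function(x) all(x %in% c(NUCS, "N")), logical(1))
  if (!all(ok)) stop("sites may only contain A, C, G, T or N")
  gaps <- lapply(chars, function(x) x == "N")
  for (g in gaps[-1]) {
    if (!identical(g, gaps[[1]]))
      stop("gap (N) columns must be identical across all sites")
  }
  structure(sites, class = "binding_site_set")
}

#' Read binding sites from a file
#'
#' Accepts FASTA or plain one-sequence-per-line text.
#' @param path File path.
#' @return A `binding_site_set`.
#' @export
read_sites <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty site file: ", path)
  if (startsWith(trimws(lines[[1]]), ">")) {
    ss <- Biostrings::readBStringSet(path)
    binding_sites(as.character(ss))
  } else {
    binding_sites(trimws(lines))
  }
}

#' Build a pseudo-counted position frequency matrix
#'
#' For each informative (non-gap) column `k` the smoothed frequency of
#' nucleotide `x` is
#' \deqn{\nu_{x,k} = (n_{x,k} + \zeta \nu_x) / (\sum_y n_{y,k} + \zeta)}
#' where `n_{x,k}` are the observed counts across the aligned sites,
#' `zeta` is the pseudo-count weight and `nu_x` the genomic background
#' frequency. With `zeta = 0` zero counts give zero frequencies; scoring a
#' sequence that uses such an entry fails at scoring time.
#'
#' @param sites A `binding_site_set` (or character vector coerced to one).
#' @param zeta Non-negative pseudo-count weight (default 1).
#' @param bg An `nt_background`.
#' @return Object of class `pfm`: list with `counts` and `freq` (4 x L
#'   matrices, `NA` in gap columns), `gap_mask`, `L`, `zeta`, `bg`,
#'   `n_sites`.
#' @export
build_pfm <- function(sites, zeta = 1, bg = ecoli_background()) {
  if (!inherits(sites, "binding_site_set")) sites <- binding_sites(sites)
  if (zeta < 0) stop("zeta must be non-negative")
  L <- nchar(sites[[1]])
  chars <- do.call(rbind, strsplit(unclass(sites), "", fixed = TRUE))
  gap_mask <- chars[1L, ] == "N"
  counts <- matrix(NA_real_, 4L, L, dimnames = list(NUCS, NULL))
  freq <- matrix(NA_real_, 4L, L, dimnames = list(NUCS, NULL))
  for (k in which(!gap_mask)) {
    n <- vapply(NUCS, function(x) sum(chars[, k] == x), numeric(1))
    counts[, k] <- n
    freq[, k] <- (n + zeta * as.numeric(bg)) / (sum(n) + zeta)
  }
  structure(
    list(counts = counts, freq = freq, gap_mask = gap_mask, L = L,
         zeta = zeta, bg = bg, n_sites = length(sites)),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix: L =", x$L, "bp,",
      sum(x$gap_mask), "gap columns,", x$n_sites, "sites, zeta =",
      x$zeta, "\n")
  invisible(x)
}

#' Per-column information content of a PFM
#'
#' @param pfm A `pfm`.
#' @return Numeric vector (bits) per column; 0 at gap columns.
#' @export
pfm_information <- function(pfm) {
  ic <- numeric(pfm$L)
  for (k in which(!pfm$gap_mask)) {
    f <- pfm$freq[, k]
    ic[k] <- sum(ifelse(f > 0, f * log2(f / as.numeric(pfm$bg)), 0))
  }
  ic
}

# Log-ratio weight matrix (4 x L), 0 in gap columns so gaps contribute
# nothing to any window score.
.pfm_weights <- function(pfm, bg) {
  W <- matrix(0, 4L, pfm$L, dimnames = list(NUCS, NULL))
  inf_cols <- which(!pfm$gap_mask)
  W[, inf_cols] <- log(pfm$freq[, inf_cols] / as.numeric(bg))
  W
}

#' Score a sequence into a binding-energy landscape
#'
#' Computes, for every motif-sized window on both strands, the log-ratio
#' binding score
#' \deqn{E(j) = \sum_k \ln(\nu_{x_{j+k},k} / \nu_{x_{j+k}})}
#' in units of kT, where the sum runs over the informative motif columns.
#' Higher scores are stronger sites; the mean of `exp(E)` over background
#' sequence is 1 by construction. The reverse strand is scored by
#' reverse-complementing the window; positions always refer to the
#' forward-strand start coordinate of the window.
#'
#' @param seq Character DNA string (A/C/G/T) or a `genome_seq`.
#' @param pfm A `pfm`.
#' @param bg Background used as the scoring reference; defaults to the
#'   background stored in the PFM.
#' @return Object of class `energy_landscape`: list with numeric vectors
#'   `fwd` and `rev` of length `M - L + 1` (index i = 1-based window start),
#'   motif length `L` and sequence length `M`.
#' @export
score_landscape <- function(seq, pfm, bg = pfm$bg) {
  if (inherits(seq, "genome_seq")) seq <- seq$seq
  seq <- toupper(seq)
  M <- nchar(seq)
  L <- pfm$L
  if (M < L) stop("sequence shorter than motif (", M, " < ", L, ")")
  code <- .seq_to_code(seq)
  if (anyNA(code))
    stop("sequence contains non-ACGT character at position ",
         which(is.na(code))[1])
  W <- .pfm_weights(pfm, bg)
  fwd <- .score_strand(code, W, pfm$gap_mask)
  code_rc <- rev(5L - code)
  rev_scan <- .score_strand(code_rc, W, pfm$gap_mask)
  if (any(!is.finite(fwd)) || any(!is.finite(rev_scan))) {
    # a zero pseudo-counted frequency was hit by an actual window
    used <- sort(unique(code))
    bad <- which(!is.na(pfm$freq) & pfm$freq == 0 &
                   row(pfm$freq) %in% used, arr.ind = TRUE)
    stop("zero motif frequency encountered while scoring (nucleotide ",
         NUCS[bad[1, 1]], ", column ", bad[1, 2],
         "); rebuild the PFM with zeta > 0")
  }
  # window [j, j+L) of the reverse complement corresponds to forward-start
  # M - L - j (0-based), i.e. a flip of the scanned vector
  structure(
    list(fwd = fwd, rev = rev(rev_scan), L = L, M = M),
    class = "energy_landscape"
  )
}

.score_strand <- function(code, W, gap_mask) {
  n <- length(code) - ncol(W) + 1L
  E <- numeric(n)
  for (k in which(!gap_mask)) {
    E <- E + unname(W[, k])[code[k:(k + n - 1L)]]
  }
  E
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("Energy landscape:", x$M, "bp,", length(x$fwd),
      "windows per strand, motif L =", x$L, "bp\n")
  cat("  score range [", round(min(x$fwd, x$rev), 3), ",",
      round(max(x$fwd, x$rev), 3), "] kT\n")
  invisible(x)
}

#' Location of the strongest site in a landscape
#'
#' Ties are broken by smallest start position, forward strand before
#' reverse.
#'
#' @param landscape An `energy_landscape`.
#' @return List with `position` (1-based window start), `strand`
#'   (`"+"`/`"-"`) and `score`.
#' @export
strongest_site <- function(landscape) {
  if (length(landscape$fwd) == 0L) stop("empty landscape")
  imax_f <- which.max(landscape$fwd)  # which.max: first max = smallest pos
  imax_r <- which.max(landscape$rev)
  best_f <- landscape$fwd[imax_f]
  best_r <- landscape$rev[imax_r]
  if (best_r > best_f || (best_r == best_f && imax_r < imax_f)) {
    list(position = imax_r, strand = "-", score = best_r)
  } else {
    list(position = imax_f, strand = "+", score = best_f)
  }
}

#' Export an energy landscape as TSV
#'
#' Writes columns `position` (0-based window start), `strand`, `score`.
#' @param landscape An `energy_landscape`.
#' @param path Output path.
#' @export
write_landscape <- function(landscape, path) {
  n <- length(landscape$fwd)
  df <- data.frame(
    position = rep(0:(n - 1L), 2L),
    strand = rep(c("+", "-"), each = n),
    score = c(landscape$fwd, landscape$rev)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a PFM as a position-by-nucleotide TSV
#'
#' Gap columns are written with `NA` frequencies.
#' @param pfm A `pfm`.
#' @param path Output path.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = 0:(pfm$L - 1L), gap = pfm$gap_mask,
                   t(pfm$freq))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
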