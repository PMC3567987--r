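test_that("pseudo-counted PFM frequencies follow the smoothing formula", {
  # single informative column with counts (T:3), zeta = 1, nu_T = 0.246:
  # nu = (3 + 1*0.246) / (3 + 1) = 0.8115
  pfm <- build_pfm(c("T", "T", "T"), zeta = 1)
  expect_equal(unname(pfm$freq["T", 1]), (3 + 0.246) / 4)
  expect_equal(unname(pfm$freq["A", 1]), 0.246 / 4)
  # zeta = 0: no smoothing
  pfm0 <- build_pfm(c("T", "T", "T"), zeta = 0)
  expect_equal(unname(pfm0$freq["T", 1]), 1)
  expect_equal(unname(pfm0$freq["A", 1]), 0)
})

test_that("every informative PFM column sums to one", {
  for (z in c(0, 0.5, 1, 7)) {
    pfm <- build_pfm(lacI_sites(), zeta = z)
    sums <- colSums(pfm$freq[, !pfm$gap_mask])
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(is.na(pfm$freq[, pfm$gap_mask])))
  }
})

test_that("site validation rejects inconsistent input", {
  expect_error(binding_sites(c("ACGT", "ACG")), "identical length")
  expect_error(binding_sites(c("ANGT", "ACGT")), "gap")
  expect_error(binding_sites(c("ACXT")), "only contain")
  expect_error(binding_sites(character(0)), "at least one")
})

test_that("scoring a motif identical to background gives zero everywhere", {
  # a PFM whose frequencies equal the background has log-ratio 0
  bg <- nt_background(0.25, 0.25, 0.25, 0.25)
  pfm <- build_pfm(c("A", "C", "G", "T"), zeta = 0, bg = bg)
  ls <- score_landscape("ACGTACGTAC", pfm, bg = bg)
  expect_true(all(abs(ls$fwd) < 1e-12))
  expect_true(all(abs(ls$rev) < 1e-12))
})

test_that("gap columns contribute nothing to scores", {
  gapped <- build_pfm(lacI_sites())
  ungapped <- build_pfm(substr(lacI_sites(), 1, 6))
  seq <- small_lac_genome(2000, seed = 3)$seq
  full <- score_landscape(seq, gapped)
  left <- score_landscape(seq, ungapped)
  # left 6-mer block at window start j plus right block at j+15 equals the
  # full gapped score
  n <- length(full$fwd)
  right <- score_landscape(seq, build_pfm(substr(lacI_sites(), 16, 21)))
  expect_equal(full$fwd, left$fwd[1:n] + right$fwd[16:(n + 15)])
})

test_that("strand symmetry: reverse strand scores the reverse complement", {
  pfm <- lacI_pfm()
  g <- synthesize_genome(500, seed = 11)
  ls <- score_landscape(g, pfm)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$seq)))
  ls_rc <- score_landscape(rc, pfm)
  # window at position j on the reverse strand is the forward window at
  # M - L - j (0-based) of the reverse complement
  expect_equal(ls$rev, rev(ls_rc$fwd))
  expect_equal(ls$fwd, rev(ls_rc$rev))
})

test_that("lacI PWM ranks O1 above the other operators", {
  pfm <- lacI_pfm()
  ops <- lacI_sites(gapped = FALSE)
  sc <- vapply(ops, function(s) score_landscape(s, pfm)$fwd[1], numeric(1))
  expect_gt(sc[["O1"]], sc[["O2"]])
  expect_gt(sc[["O1"]], sc[["O3"]])
})

test_that("mean of exp(E) over i.i.d. background sequence is one", {
  # analytic identity: E[exp E] = prod_k sum_x nu_{x,k} = 1; checked by
  # Monte Carlo over >= 1e5 windows
  pfm <- lacI_pfm()
  g <- synthesize_genome(100020, seed = 202)
  ls <- score_landscape(g, pfm)
  v <- exp(c(ls$fwd, ls$rev))
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 1), 3 * se)
})

test_that("zero-count zeta=0 PFM errors at scoring time, naming a column", {
  # palindromic motif: the only window matching on both strands scores fine
  pal <- build_pfm(c("AT", "AT"), zeta = 0)
  expect_silent(ls <- score_landscape("AT", pal))
  expect_equal(ls$fwd, ls$rev)
  # any window that touches a zero-count cell fails, naming the column
  expect_error(score_landscape("GTGTGT", build_pfm("AC", zeta = 0)),
               "column")
  expect_error(score_landscape("ACACAC", build_pfm(c("AC", "AC"), zeta = 0)),
               "column")
})

test_that("strongest_site returns the maximum with deterministic ties", {
  pfm <- lacI_pfm()
  g <- small_lac_genome(20000, seed = 101)
  ls <- score_landscape(g, pfm)
  hit <- strongest_site(ls)
  expect_equal(unname(hit$position), 10000)
  expect_equal(hit$strand, "+")
  # constant landscape: position 1, forward strand
  flat <- structure(list(fwd = rep(1, 5), rev = rep(1, 5), L = 2, M = 6),
                    class = "energy_landscape")
  tie <- strongest_site(flat)
  expect_equal(tie$position, 1)
  expect_equal(tie$strand, "+")
})

test_that("PFM and landscape exports round-trip through TSV", {
  pfm <- lacI_pfm()
  g <- synthesize_genome(200, seed = 9)
  ls <- score_landscape(g, pfm)
  tf <- tempfile(fileext = ".tsv")
  write_landscape(ls, tf)
  back <- read.table(tf, header = TRUE)
  expect_equal(back$score[back$strand == "+"], ls$fwd)
  expect_equal(back$position[1], 0)  # 0-based export
  tf2 <- tempfile(fileext = ".tsv")
  write_pfm(pfm, tf2)
  back2 <- read.table(tf2, header = TRUE)
  expect_equal(nrow(back2), pfm$L)
  expect_equal(back2$A[!back2$gap], unname(pfm$freq["A", !pfm$gap_mask]))
})

test_that("bundled operator site files load through read_sites", {
  gap <- read_sites(system.file("extdata", "lacI_operators_gapped.txt",
                                package = "fdsim"))
  expect_equal(unclass(gap), unname(lacI_sites()))
  fa <- read_sites(system.file("extdata", "lacI_operators.fa",
                               package = "fdsim"))
  expect_equal(unclass(fa), lacI_sites(gapped = FALSE),
               ignore_attr = TRUE)
})
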