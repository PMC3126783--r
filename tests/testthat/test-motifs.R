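two_pwm_file <- function() {
  path <- tempfile(fileext = ".txt")
  writeLines(c(
    ">MX1 TFalpha test matrix",
    "0.7000\t0.1000\t0.1000\t0.1000",
    "0.0500\t0.8500\t0.0500\t0.0500",
    "0.1000\t0.1000\t0.7000\t0.1000",
    "0.2500\t0.2500\t0.2500\t0.2500",
    "",
    ">MX2 TFbeta",
    "0.0000\t0.0000\t0.0000\t1.0000",
    "1.0000\t0.0000\t0.0000\t0.0000",
    "0.0000\t1.0000\t0.0000\t0.0000",
    "0.0000\t0.0000\t1.0000\t0.0000",
    "0.5000\t0.5000\t0.0000\t0.0000"), path)
  path
}

test_that("PWM text files parse, renormalize and round-trip", {
  pwms <- read_pwms(two_pwm_file())
  expect_length(pwms, 2)
  expect_equal(pwm_widths <- sapply(pwms, function(p) nrow(p$mat)),
               c(MX1 = 4L, MX2 = 5L))
  expect_equal(pwms$MX1$name, "TFalpha")
  expect_true(all(abs(rowSums(pwms$MX1$mat) - 1) < 1e-12))
  out <- tempfile()
  write_pwms(pwms, out)
  back <- read_pwms(out)
  expect_equal(back$MX2$mat, pwms$MX2$mat, tolerance = 1e-6)
  # malformed inputs
  bad <- tempfile(); writeLines(c(">B1 x", "0.5 0.5 0.5"), bad)
  expect_error(read_pwms(bad), "4 numeric fields")
  expect_error(pwm("N1", "x", matrix(c(-0.1, 0.5, 0.3, 0.3), 1)), "negative")
  expect_error(pwm("N2", "x", matrix(numeric(0), 0, 4)), "empty")
})

test_that("information content follows the entropy closed form", {
  p <- pwm("IC1", "x", rbind(c(1, 0, 0, 0),
                             c(0.25, 0.25, 0.25, 0.25),
                             c(0.5, 0.5, 0, 0)))
  expect_equal(information_content(p), c(2, 0, 1))
})

test_that("a consensus sequence scores a perfect hit on either strand", {
  p <- degenerate_pwm("ACGTGA")
  hits <- scan_relative(c(s1 = "ACGTGA"), p, 0.8)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$rel_score, 1.0)
  expect_equal(hits$strand, 1L)
  expect_equal(hits$start, 1L)
  rc <- scan_relative(c(s1 = rev_comp("ACGTGA")), p, 0.8)
  expect_equal(rc$strand, -1L)
  expect_equal(rc$rel_score, 1.0)
})

test_that("window scores equal the brute-force per-window oracle", {
  seq <- random_dna(500, seed = 23)
  pwms <- synthetic_pwms(3, seed = 8)
  for (p in pwms) {
    hits <- scan_relative(c(q = seq), p, threshold = 0)
    w <- nrow(p$mat)
    expect_equal(nrow(hits), 2 * (500 - w + 1))  # every window, both strands
    oracle_plus <- oracle_window_scores_plus(seq, p$mat)
    got_plus <- hits$raw_score[hits$strand == 1][order(hits$start[hits$strand == 1])]
    expect_equal(got_plus, oracle_plus, tolerance = 1e-12)
    oracle_minus <- oracle_window_scores_plus(rev_comp(seq), p$mat)
    got_minus <- hits[hits$strand == -1, ]
    # minus-strand window at plus start s is rc window 500 - w + 2 - s
    for (i in sample(nrow(got_minus), 20)) {
      j <- 500 - w + 2 - got_minus$start[i]
      expect_equal(got_minus$raw_score[i], oracle_minus[j], tolerance = 1e-12)
    }
  }
})

test_that("strand closure: scanning the reverse complement mirrors hits", {
  seqs <- c(a = random_dna(300, 31), b = random_dna(250, 32))
  p <- synthetic_pwms(1, seed = 14)[[1]]
  fwd <- scan_relative(seqs, p, 0.5)
  rev <- scan_relative(setNames(rev_comp(seqs), names(seqs)), p, 0.5)
  L <- nchar(seqs)
  key_fwd <- paste(fwd$seq_id, fwd$start, fwd$strand, signif(fwd$raw_score, 12))
  key_rev <- paste(rev$seq_id, L[rev$seq_id] - rev$end + 1, -rev$strand,
                   signif(rev$raw_score, 12))
  expect_setequal(key_fwd, key_rev)
})

test_that("hits contract monotonically as thresholds tighten", {
  seqs <- c(a = random_dna(400, 41, gc = 0.33))
  p <- synthetic_pwms(1, seed = 15)[[1]]
  prev <- nrow(scan_relative(seqs, p, 0.5))
  for (th in c(0.6, 0.7, 0.8, 0.9)) {
    cur <- nrow(scan_relative(seqs, p, th))
    expect_lte(cur, prev)
    prev <- cur
  }
  # windows containing N are skipped
  seqN <- c(n1 = paste0(substr(seqs[[1]], 1, 100), "NNNN",
                        substr(seqs[[1]], 105, 400)))
  hitsN <- scan_relative(seqN, p, 0)
  w <- nrow(p$mat)
  expect_equal(nrow(hitsN), 2 * (400 - w + 1 - (w + 3)))
})

test_that("Markov training produces proper conditionals", {
  m0 <- train_markov(c("AAAAAAAAAAAAAAAAAAAA"), order = 0)
  expect_true(all(abs(rowSums(m0$cond[[1]]) - 1) < 1e-9))
  expect_gt(m0$cond[[1]][1, 1], 0.8)             # A dominates despite smoothing
  s <- sample_markov(m0, 1000, seed = 2)
  expect_gt(mean(strsplit(s, "")[[1]] == "A"), 0.8)
  m2 <- suppressWarnings(train_markov(c("ACGTACGTACGT"), order = 2))
  for (tab in m2$cond) expect_true(all(abs(rowSums(tab) - 1) < 1e-9))
})

test_that("sampled sequences reproduce training k-mer structure", {
  train <- sample_markov(markov_from_composition(0.4, 0), 100000, seed = 3)
  model <- train_markov(train, order = 4)
  samp <- sample_markov(model, 100000, seed = 5)
  kmer_freq <- function(s) {
    code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    win <- embed(code, 5)
    idx <- as.vector((win[, 5] - 1) * 256 + (win[, 4] - 1) * 64 +
                       (win[, 3] - 1) * 16 + (win[, 2] - 1) * 4 + win[, 1])
    tabulate(idx, 1024) / nrow(win)
  }
  expect_gte(cor(kmer_freq(train[[1]]), kmer_freq(samp[[1]])), 0.95)
})

test_that("composition-model samples match the target within 0.01", {
  model <- markov_from_composition(0.33, 4)
  s <- sample_markov(model, 200000, seed = 7)
  expect_equal(gc_content(s), 0.33, tolerance = 0.01)
  # determinism and per-length multiplicity
  a <- sample_markov(model, c(50, 60), n = 4, seed = 9)
  b <- sample_markov(model, c(50, 60), n = 4, seed = 9)
  expect_identical(a, b)
  expect_equal(nchar(a), c(50, 60, 50, 60))
})

test_that("FDR calling controls background hits and guards empties", {
  model <- markov_from_composition(0.33, 2)
  p <- degenerate_pwm("ACGTAGGT", id = "D8")
  # plant the consensus in every sequence
  set.seed(10)
  seqs <- sample_markov(model, 200, n = 30, seed = 11)
  names(seqs) <- sprintf("s%02d", 1:30)
  starts <- sample(1:(200 - 8 + 1), 30, replace = TRUE)
  for (i in 1:30) substr(seqs[i], starts[i], starts[i] + 7) <- "ACGTAGGT"
  hits <- call_fdr(seqs, p, model, n_bg = 10, fdr_max = 0.15, seed = 12)
  key <- paste(names(seqs), starts, 1)
  recovered <- mean(key %in% paste(hits$seq_id, hits$start, hits$strand))
  expect_gte(recovered, 0.8)                     # planted sites recovered
  # background-only input: no or almost no calls for a sharp PWM
  bg_only <- sample_markov(model, 200, n = 30, seed = 13)
  names(bg_only) <- sprintf("b%02d", 1:30)
  h0 <- call_fdr(bg_only, p, model, n_bg = 10, fdr_max = 0.15, seed = 14)
  expect_lte(nrow(h0), 5)
  # all-N input has no scoreable window: empty result, no division error
  expect_equal(nrow(call_fdr(c(x = strrep("N", 50)), p, model, seed = 1)), 0)
})

test_that("lowering fdr_max never adds calls", {
  model <- markov_from_composition(0.33, 2)
  p <- synthetic_pwms(1, seed = 21)[[1]]
  seqs <- sample_markov(model, 300, n = 20, seed = 22)
  names(seqs) <- sprintf("s%02d", 1:20)
  bg <- sample_markov(model, rep(300, 200), n = 200, seed = 23)
  prev <- Inf
  for (f in c(0.5, 0.3, 0.15, 0.05)) {
    cur <- nrow(call_fdr(seqs, p, model, fdr_max = f, backgrounds = bg))
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("consensus matching equals the quadratic oracle", {
  h <- function(seq_id, pwm_id, start, strand)
    data.frame(seq_id = seq_id, pwm_id = pwm_id, start = start,
               strand = strand, stringsAsFactors = FALSE)
  a <- h("s1", "M1", c(5, 10, 20), c(1, -1, 1))
  expect_equal(consensus_hits(a, a), a)          # identical lists
  b <- h("s1", "M1", c(6, 11, 21), c(1, -1, 1))
  expect_equal(nrow(consensus_hits(a, b)), 0)    # disjoint coordinates
  set.seed(33)
  big_a <- h(sample(paste0("s", 1:5), 40, TRUE), sample(c("M1", "M2"), 40, TRUE),
             sample(1:30, 40, TRUE), sample(c(1L, -1L), 40, TRUE))
  big_b <- h(sample(paste0("s", 1:5), 40, TRUE), sample(c("M1", "M2"), 40, TRUE),
             sample(1:30, 40, TRUE), sample(c(1L, -1L), 40, TRUE))
  expect_equal(consensus_hits(big_a, big_b), oracle_consensus(big_a, big_b))
})

test_that("the mean-plus-SD rule flags only outlying counts", {
  pwms <- lapply(1:4, function(i) degenerate_pwm("ACGTGA", sprintf("P%d", i)))
  names(pwms) <- paste0("P", 1:4)
  class(pwms) <- "pwm_collection"
  mk <- function(counts) {
    do.call(rbind, lapply(seq_along(counts), function(i) {
      if (counts[i] == 0) return(NULL)
      data.frame(seq_id = "s1", pwm_id = names(pwms)[i],
                 start = seq_len(counts[i]), strand = 1L,
                 stringsAsFactors = FALSE)
    }))
  }
  tab <- enrichment(mk(c(5, 1, 1, 1)), pwms)
  # mean 2, sample sd 2: threshold 4, only the count of 5 exceeds it
  expect_equal(attr(tab, "mean"), 2)
  expect_equal(attr(tab, "sd"), 2)
  expect_equal(tab$pwm_id[tab$overrepresented], "P1")
  tab_eq <- enrichment(mk(c(3, 3, 3, 3)), pwms)
  expect_false(any(tab_eq$overrepresented))      # count > mean + 0 never holds
  # monotone in a single raised count
  flagged <- sapply(c(2, 4, 6, 8, 12), function(k)
    enrichment(mk(c(k, 1, 1, 1)), pwms)$overrepresented[1])
  expect_true(all(diff(as.integer(flagged)) >= 0))
  expect_error(enrichment(mk(c(1, 0, 0, 0)), pwms[1]), "2 PWMs")
})

test_that("AW-box scanning finds the pattern on both strands", {
  direct <- "CATAGAAAAAAAC"
  hits <- scan_aw_box(c(s1 = direct))
  expect_equal(hits$start, 1L)
  expect_equal(hits$strand, 1L)
  rc <- scan_aw_box(c(s1 = rev_comp(direct)))
  expect_equal(rc$strand, -1L)
  expect_equal(rc$start, 1L)
  # 10 kb random sequence vs the character-level oracle
  seq <- random_dna(10000, seed = 51, gc = 0.33)
  got <- scan_aw_box(c(q = seq))
  plus <- sort(got$start[got$strand == 1])
  expect_equal(plus, oracle_aw_box_plus(seq))
  minus_expected <- sort(10000 - (oracle_aw_box_plus(rev_comp(seq)) + 12) + 1)
  expect_equal(sort(got$start[got$strand == -1]), minus_expected)
})

test_that("G+C content pools bases and ignores N", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content(c("GGNN", "AANN")), 0.5)
  expect_error(gc_content("NNNN"), "countable")
})
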