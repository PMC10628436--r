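test_that("planted hairpins are true inverted repeats at recorded coordinates", {
  cfg <- small_sim_config(seed = 31, n_dsrna = 3, n_splice = 2, n_noise = 2,
                          genome_length = 60000)
  sim <- simulate_genome(cfg)
  truth <- sim$truth
  expect_true(all(diff(truth$start) > 0))
  # loci never overlap and respect the spacing floor
  expect_true(all(truth$start[-1] - truth$end[-nrow(truth)] >=
                    cfg$locus_spacing))
  for (k in which(truth$kind == "dsRNA")) {
    seq <- as.character(Biostrings::subseq(sim$genome[[1]],
                                           truth$start[k] + 1, truth$end[k]))
    arm <- truth$arm_length[k]
    left <- substr(seq, 1, arm)
    right <- substr(seq, nchar(seq) - arm + 1, nchar(seq))
    expect_equal(
      chartr("ACGT", "TGCA",
             paste(rev(strsplit(left, "")[[1]]), collapse = "")),
      right
    )
  }
  for (k in which(truth$kind == "splice")) {
    intron <- as.character(Biostrings::subseq(
      sim$genome[[1]], truth$event_start[k] + 1, truth$event_end[k]
    ))
    expect_equal(substr(intron, 1, 2), "GT")
    expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
  }
})

test_that("generation does not fit oversized locus sets", {
  cfg <- small_sim_config(seed = 1, genome_length = 30000)
  expect_error(simulate_genome(cfg), "do not fit")
})

test_that("a planted hairpin folds into a qualifying long stem", {
  cfg <- small_sim_config(seed = 33, n_dsrna = 2, n_splice = 1, n_noise = 1,
                          genome_length = 50000,
                          arm_length_range = c(250, 300),
                          loop_range = c(60, 100))
  sim <- simulate_genome(cfg)
  tr <- sim$truth[sim$truth$kind == "dsRNA", ][1, ]
  fold <- fold_sequence(
    as.character(Biostrings::subseq(sim$genome[[1]], tr$start + 1, tr$end))
  )
  stem <- stem_report(fold$dotbracket)
  expect_gte(stem$length, 200)
})

test_that("splice reads reuse exact junctions while hairpin skips jitter", {
  corpus <- get_small_corpus()
  aln <- corpus$alignments
  truth <- corpus$truth
  ev <- skip_events(corpus$reads)
  for (k in which(truth$kind == "splice")) {
    in_locus <- ev[ev$start >= truth$start[k] & ev$start < truth$end[k], ]
    if (nrow(in_locus) == 0) next
    expect_true(all(in_locus$start == truth$event_start[k]))
    expect_true(all(in_locus$end == truth$event_end[k]))
  }
  jitters <- c()
  for (k in which(truth$kind == "dsRNA")) {
    in_locus <- ev[ev$start > truth$start[k] - 200 &
                     ev$start < truth$start[k] + 200, ]
    jitters <- c(jitters, in_locus$start - truth$start[k])
  }
  expect_gt(length(jitters), 3)
  expect_gt(sd(jitters), 5)             # boundaries do not align across reads
  expect_lt(max(abs(jitters)), 5 * 30)  # but stay near the hairpin edge
})

test_that("per-locus skipping read counts stay inside binomial bounds", {
  cfg <- small_sim_config(seed = 35, n_dsrna = 6, n_splice = 2, n_noise = 2,
                          genome_length = 120000, mean_coverage = 60,
                          skip_fraction_range = c(0.099, 0.101))
  sim <- simulate_genome(cfg)
  sites <- simulate_editing_sites(sim$genome, sim$truth, cfg)
  aln <- simulate_alignments(sim$genome, sim$truth, cfg, sites = sites)
  for (k in which(sim$truth$kind == "dsRNA")) {
    reads_k <- aln[aln$locus == k, ]
    n <- nrow(reads_k)
    skipped <- sum(reads_k$skipped)
    bounds <- qbinom(c(0.0005, 0.9995), n, 0.1)
    expect_gte(skipped, bounds[1])
    expect_lte(skipped, bounds[2])
  }
})

test_that("every emitted record round-trips with identical events from cs and CIGAR", {
  corpus <- get_small_corpus()
  aln <- corpus$alignments
  for (i in seq_len(nrow(aln))) {
    from_cigar <- parse_skip_events(aln$cigar[i], aln$pos[i])
    from_cs <- parse_skip_events(cs = aln$cs[i], pos = aln$pos[i])
    expect_equal(from_cigar[, c("start", "end")], from_cs[, c("start", "end")],
                 info = aln$read_id[i])
  }
})

test_that("editing sites are dense enough for enrichment and absent elsewhere", {
  corpus <- get_small_corpus()
  truth <- corpus$truth
  sites <- corpus$sites
  for (k in which(truth$kind == "dsRNA")) {
    s <- sites[sites$locus == k, ]
    expect_gte(nrow(s), 3)
    eer <- find_editing_enriched(s)
    expect_gte(nrow(eer), 1)
    expect_true(all(s$pos >= truth$start[k] & s$pos < truth$end[k]))
  }
  outside <- !vapply(seq_len(nrow(sites)), function(i) {
    any(truth$kind == "dsRNA" & truth$start <= sites$pos[i] &
          truth$end > sites$pos[i])
  }, logical(1))
  expect_equal(sum(outside), 0L)
})

test_that("read sequences carry planted A-to-G substitutions at catalog sites", {
  corpus <- get_small_corpus()
  genome_str <- as.character(corpus$genome[[1]])
  aln <- corpus$alignments
  sites <- corpus$sites
  # the cs tags record each substitution; realised counts stay within the
  # 99% binomial envelope of the planted level at well-covered sites
  aln$ref_end <- aln$pos + vapply(aln$cigar, cigar_reference_span, numeric(1))
  checked <- 0L
  for (i in seq_len(nrow(sites))) {
    pos <- sites$pos[i]
    covering <- aln[aln$pos <= pos - 1 & aln$ref_end > pos + 1, ]
    if (nrow(covering) < 8) next
    edited <- 0L
    informative <- 0L
    for (r in seq_len(nrow(covering))) {
      ev <- parse_skip_events(covering$cigar[r], covering$pos[r])
      if (nrow(ev) > 0 && any(ev$start <= pos & ev$end > pos)) next
      informative <- informative + 1L
      offset <- pos - covering$pos[r]
      # reconstruct the read base at the site from the record
      read_seq <- covering$seq[r]
      if (nrow(ev) > 0 && ev$start[1] <= pos) {
        offset <- offset - sum(ev$length[ev$start <= pos])
      }
      base <- substr(read_seq, offset + 1, offset + 1)
      if (base == "G") edited <- edited + 1L
    }
    if (informative < 8) next
    bounds <- qbinom(c(0.005, 0.995), informative, sites$level[i])
    expect_gte(edited, bounds[1])
    expect_lte(edited, bounds[2])
    checked <- checked + 1L
    if (checked >= 25) break
  }
  expect_gte(checked, 10)
})

test_that("corpus artifacts are byte-identical across reruns of the same seed", {
  cfg <- small_sim_config(seed = 37, n_dsrna = 3, n_splice = 3, n_noise = 3,
                          genome_length = 70000)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- simulate_corpus(cfg, d1)
  c2 <- simulate_corpus(cfg, d2)
  for (n in c("genome", "alignments", "truth", "sites", "manifest")) {
    expect_identical(readBin(c1$paths[[n]], "raw", 5e7),
                     readBin(c2$paths[[n]], "raw", 5e7), info = n)
  }
})
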