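test_that("window tiling follows the stride and keeps only long partials", {
  expect_equal(window_starts(5000), c(0, 1250, 2500))
  expect_equal(window_starts(6000), c(0, 1250, 2500, 3750))
  expect_equal(window_starts(2500), 0)
  expect_equal(window_starts(2000), 0)     # partial, longer than one step
  expect_equal(window_starts(1250), numeric(0))
  # every base of a long chromosome is covered once or twice
  starts <- window_starts(20000)
  cover <- rep(0L, 20000)
  for (s in starts) cover[(s + 1):min(s + 2500, 20000)] <-
    cover[(s + 1):min(s + 2500, 20000)] + 1L
  expect_true(all(cover >= 1L & cover <= 2L))
})

test_that("candidate windows obey the six-read / one-skip floor exactly", {
  genome <- Biostrings::DNAStringSet(c(mini = paste(
    rep("ACGT", 1500), collapse = ""
  )))
  mk_reads <- function(n_reads, n_skipping) {
    make_read_table("mini", lapply(seq_len(n_reads), function(i) {
      if (i <= n_skipping) {
        list(start = 100, end = 2300, skips = list(c(500 + i, 1000 + i)))
      } else {
        list(start = 100, end = 2300)
      }
    }))
  }
  cand <- enumerate_candidate_windows(mk_reads(6, 1), genome,
                                      window = 2500, step = 1250)
  expect_gte(nrow(cand), 1)
  expect_error(enumerate_candidate_windows(mk_reads(5, 1), genome),
               "no window")
  expect_error(enumerate_candidate_windows(mk_reads(6, 0), genome),
               "no window")
})

test_that("discovery keeps strictly-above-threshold, non-EER windows, sorted", {
  genome <- Biostrings::DNAStringSet(c(sim1 = strrep("A", 30000)))
  cand <- fake_candidates(c(0, 2500, 5000, 7500, 10000))
  model <- fake_model(c("0" = 0.49, "2500" = 0.5, "5000" = 0.51,
                        "7500" = 0.9, "10000" = 0.7))
  positives <- tibble::tibble(chrom = "sim1", start = 10100, end = 10500)
  out <- discover_dsrna(cand, model, positives, genome, fold = FALSE)
  # 0.49 and exactly-0.5 excluded; the 10000 window overlaps a positive
  expect_equal(out$start, c(7500, 5000))
  expect_equal(out$probability, c(0.9, 0.51))
  # probability column, not classification, when folding is off
  expect_true(all(is.na(out$class)))
})

test_that("discovered windows never overlap curated positives", {
  genome <- Biostrings::DNAStringSet(c(sim1 = strrep("A", 30000)))
  set.seed(2)
  starts <- seq(0, 20000, by = 1250)
  probs <- setNames(round(runif(length(starts)), 3), as.character(starts))
  model <- fake_model(probs)
  cand <- fake_candidates(starts)
  positives <- tibble::tibble(chrom = "sim1",
                              start = c(3000, 11000), end = c(5200, 13100))
  out <- discover_dsrna(cand, model, positives, genome, fold = FALSE)
  for (k in seq_len(nrow(out))) {
    expect_false(any(positives$start < out$end[k] &
                       positives$end > out$start[k]))
  }
  expect_true(all(diff(out$probability) <= 0))
})

test_that("surviving windows are folded and classified; failures skip the window", {
  genome <- Biostrings::DNAStringSet(c(sim1 = paste(
    rep(c("A", "C", "G", "T"), 2500), collapse = ""
  )))
  cand <- fake_candidates(c(0, 2500))
  model <- fake_model(c("0" = 0.8, "2500" = 0.9))
  hairpin_engine <- function(seq) {
    n <- nchar(seq)
    half <- 1000
    list(dotbracket = paste0(strrep("(", half),
                             strrep(".", n - 2 * half),
                             strrep(")", half)),
         mfe = -0.5 * n)
  }
  out <- discover_dsrna(cand, model,
                        tibble::tibble(chrom = character(0),
                                       start = numeric(0), end = numeric(0)),
                        genome, engine = hairpin_engine)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$class == "novel_long_dsRNA"))
  expect_equal(out$stem_length, c(1000L, 1000L))
  expect_equal(out$amfe, c(-50, -50))

  failing_engine <- function(seq) stop("engine exploded")
  out2 <- suppressMessages(
    discover_dsrna(cand, model,
                   tibble::tibble(chrom = character(0), start = numeric(0),
                                  end = numeric(0)),
                   genome, engine = failing_engine)
  )
  expect_equal(nrow(out2), 0L)
})

test_that("an end-to-end scan recovers a planted hairpin as novel dsRNA", {
  corpus <- get_small_corpus()
  merged <- merge_nearby(find_editing_enriched(
    load_editing_sites(corpus$paths$sites)
  ))
  ts <- curate_training_set(merged, corpus$genome, corpus$reads, seed = 5)
  model <- train_model(ts)
  # pick a planted hairpin with observed skipping and a stem that dominates
  # its loop, so the structural filter is decidable from the window
  ev <- skip_events(corpus$reads)
  ds_all <- corpus$truth[corpus$truth$kind == "dsRNA", ]
  n_ev <- vapply(seq_len(nrow(ds_all)), function(i) {
    sum(ev$start >= ds_all$start[i] - 200 & ev$start < ds_all$end[i])
  }, numeric(1))
  ok <- which(n_ev >= 2 & ds_all$arm_length >= 300 &
                ds_all$loop_length <= ds_all$arm_length / 2)
  ds <- ds_all[ok[1], ]
  win_start <- max(0, floor((ds$start + ds$end) / 2) - 1250)
  cand <- extract_features(corpus$reads, corpus$genome, ds$chrom,
                           win_start, win_start + 2500)
  out <- discover_dsrna(cand, model,
                        tibble::tibble(chrom = character(0),
                                       start = numeric(0), end = numeric(0)),
                        corpus$genome)
  expect_equal(nrow(out), 1L)
  expect_gt(out$probability, 0.5)
  expect_equal(out$class, "novel_long_dsRNA")
})

test_that("editing indices pool qualifying sites with strand awareness", {
  chrom_len <- 400L
  ref <- paste(rep("A", chrom_len), collapse = "")
  sam <- withr::local_tempfile(fileext = ".sam")
  # 8 reads over the site at 0-based 100: 6 read A, 2 read G
  recs <- lapply(1:8, function(i) {
    seq <- strrep("A", 200)
    if (i <= 2) substr(seq, 51, 51) <- "G"
    list(id = paste0("r", i), pos = 50, cigar = "200M", seq = seq)
  })
  # site at 300 covered by exactly 3 reads; site at 310 by 4 (1 G)
  recs <- c(recs,
            lapply(1:3, function(i) {
              list(id = paste0("s", i), pos = 250, cigar = "100M",
                   seq = strrep("G", 100))
            }),
            list(list(id = "s4", pos = 305, cigar = "15M",
                      seq = paste0(strrep("A", 5), "G", strrep("A", 9)))))
  write_fixture_sam(sam, "chrF", chrom_len, recs)
  sites <- tibble::tibble(chrom = "chrF", pos = c(100, 300, 310),
                          strand = "+")
  ei <- compute_editing_index("chrF", 0, 400, sam, sites)
  # site 100: 6 A + 2 G; site 300 excluded (coverage 3); site 310: 3 G + 1 A?
  expect_equal(ei$n_sites, 2L)
  expect_equal(ei$g_count, 2L + 4L)
  expect_equal(ei$a_count, 6L + 0L)
  expect_equal(ei$editing_index, 6 / 12)

  # minus-strand site: reference T positions read as C count as edited
  sam2 <- withr::local_tempfile(fileext = ".sam")
  recs2 <- lapply(1:6, function(i) {
    seq <- strrep("T", 100)
    if (i <= 3) substr(seq, 21, 21) <- "C"
    list(id = paste0("m", i), pos = 0, cigar = "100M", seq = seq)
  })
  write_fixture_sam(sam2, "chrF", chrom_len, recs2)
  ei2 <- compute_editing_index("chrF", 0, 400, sam2,
                               tibble::tibble(chrom = "chrF", pos = 20,
                                              strand = "-"))
  expect_equal(ei2$editing_index, 0.5)

  # no qualifying site: missing, not zero
  ei3 <- compute_editing_index("chrF", 0, 90, sam,
                               tibble::tibble(chrom = "chrF", pos = 10,
                                              strand = "+")[0, ])
  expect_true(is.na(ei3$editing_index))
})

test_that("result export is deterministic BED6 + TSV with the rounding rule", {
  regions <- tibble::tibble(
    chrom = c("sim1", "sim1"), start = c(100, 5000), end = c(2600, 7500),
    probability = c(0.876, 0.6504), class = c("novel_long_dsRNA", NA),
    mfe = c(-900, NA), amfe = c(-36, NA),
    stem_length = c(250L, NA), mismatch_fraction = c(0.1, NA)
  )
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_results(regions, bed, tsv)
  lines <- readLines(bed)
  expect_length(lines, 2)
  f1 <- strsplit(lines[1], "\t")[[1]]
  expect_equal(f1[4], "novel_long_dsRNA")
  expect_equal(f1[5], "876")
  expect_equal(strsplit(lines[2], "\t")[[1]][4], "unclassified")

  bed2 <- withr::local_tempfile(fileext = ".bed")
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  export_results(regions, bed2, tsv2)
  expect_identical(readLines(bed2), lines)
  expect_identical(readLines(tsv2), readLines(tsv))

  bed3 <- withr::local_tempfile(fileext = ".bed")
  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  export_results(regions[0, ], bed3, tsv3)
  expect_length(readLines(bed3), 0)
  expect_gte(length(readLines(tsv3)), 1)  # header survives
})
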