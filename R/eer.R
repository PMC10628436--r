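#' Find editing-enriched regions (EERs)
#'
#' Scans a sorted A-to-I editing-site catalog for clusters: a region is
#' editing-enriched when at least `min_sites` sites fall within any `span`-nt
#' window. Sites on both strands are pooled for density. Overlapping or
#' abutting enriched intervals are unioned and site counts re-tallied on the
#' union.
#'
#' @param sites Editing-site tibble from [load_editing_sites()] (`chrom`,
#'   `pos`; strand ignored).
#' @param span Window span (nt).
#' @param min_sites Minimum sites within a span.
#' @return A tibble of enriched intervals: `chrom`, `start`, `end`
#'   (0-based half-open), `n_sites`.
#' @export
find_editing_enriched <- function(sites, span = 50, min_sites = 3) {
  empty <- tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  n_sites = integer(0))
  if (nrow(sites) == 0L) return(empty)
  per_chrom <- split(sites, sites$chrom)
  out <- map(per_chrom, function(s) {
    pos <- sort(unique(s$pos))
    n <- length(pos)
    if (n < min_sites) return(NULL)
    i_last <- n - min_sites + 1L
    hits <- which(pos[seq_len(i_last) + min_sites - 1L] - pos[seq_len(i_last)] < span)
    if (length(hits) == 0L) return(NULL)
    iv <- tibble(start = pos[hits], end = pos[hits + min_sites - 1L] + 1)
    merged <- merge_intervals(iv$start, iv$end, gap = 0)
    tibble(
      chrom = s$chrom[1],
      start = merged$start, end = merged$end,
      n_sites = map_int(seq_along(merged$start), function(k) {
        sum(pos >= merged$start[k] & pos < merged$end[k])
      })
    )
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(empty)
  arrange(res, .data$chrom, .data$start)
}

# union of same-chromosome intervals: merge when next.start - prev.end <= gap
merge_intervals <- function(start, end, gap = 0) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (k in seq_along(start)[-1]) {
    if (start[k] - me <= gap) {
      me <- max(me, end[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[k]; me <- end[k]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Merge nearby intervals
#'
#' Consecutive intervals on the same chromosome separated by at most `gap`
#' nt (0 for abutting) are merged into their union span. Idempotent.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param gap Maximum separation merged across (nt).
#' @return Merged interval tibble, sorted, pairwise distance > `gap`.
#' @export
merge_nearby <- function(intervals, gap = 1000) {
  if (nrow(intervals) == 0L) return(intervals[, c("chrom", "start", "end")])
  per_chrom <- split(intervals, intervals$chrom)
  bind_rows(map(per_chrom, function(iv) {
    m <- merge_intervals(iv$start, iv$end, gap = gap)
    tibble(chrom = iv$chrom[1], start = m$start, end = m$end)
  })) |>
    arrange(.data$chrom, .data$start)
}

#' Structure-verify candidate dsRNA regions
#'
#' Folds the reference sequence of each interval and retains those whose
#' predicted structure has a long, near-perfect duplex: stem length at least
#' `min_stem` bp, span mismatch fraction at most `max_mismatch`, and
#' adjusted MFE at most `amfe_max`. Intervals shorter than `pad_to` nt are
#' padded symmetrically before folding so a qualifying stem is
#' representable; intervals longer than the folding limit are skipped with a
#' logged reason rather than an error.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (merged EERs).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param engine Folding engine (default [rnafold_engine()]).
#' @param min_stem,max_mismatch,amfe_max Retention thresholds (see
#'   [classify_structure()]).
#' @param pad_to Minimum folded width (nt).
#' @param max_fold_len Maximum sequence length passed to the engine (nt).
#' @return A tibble of retained regions: `chrom`, `start`, `end` (the folded,
#'   possibly padded interval), `mfe`, `amfe`, `stem_length`,
#'   `mismatch_fraction`. Dropped intervals and their reasons are attached as
#'   the `"dropped"` attribute.
#' @export
curate_positive_regions <- function(intervals, genome, engine = NULL,
                                    min_stem = 200, max_mismatch = 0.20,
                                    amfe_max = -35.0, pad_to = 200,
                                    max_fold_len = 5000) {
  if (is.null(engine)) engine <- rnafold_engine()
  kept <- list(); dropped <- list()
  for (k in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[k]
    start <- intervals$start[k]; end <- intervals$end[k]
    if (!chrom %in% names(genome)) {
      abort(paste0("reference chromosome missing: ", chrom))
    }
    clen <- length(genome[[chrom]])
    if (end - start < pad_to) {
      start <- max(0, start - ceiling((pad_to - (end - start)) / 2))
      end <- min(clen, start + pad_to)
      start <- max(0, end - pad_to)
    }
    width <- end - start
    if (width > max_fold_len) {
      inform(paste0("skipping ", chrom, ":", start, "-", end,
                    ": length ", width, " exceeds folding limit ", max_fold_len))
      dropped[[length(dropped) + 1L]] <-
        tibble(chrom = chrom, start = start, end = end, reason = "over_fold_limit")
      next
    }
    seq <- ref_segment(genome, chrom, start, end)
    fold <- fold_sequence(seq, engine = engine, max_len = max_fold_len)
    stem <- stem_report(fold$dotbracket)
    cls <- classify_structure(fold, stem, min_stem = min_stem,
                              max_mismatch = max_mismatch, amfe_max = amfe_max)
    row <- tibble(chrom = chrom, start = start, end = end,
                  mfe = fold$mfe, amfe = fold$amfe,
                  stem_length = stem$length,
                  mismatch_fraction = stem$mismatch_fraction)
    if (cls == "novel_long_dsRNA") {
      kept[[length(kept) + 1L]] <- row
    } else {
      inform(paste0("dropping ", chrom, ":", start, "-", end,
                    ": stem ", stem$length, " bp, mismatch ",
                    round(stem$mismatch_fraction, 3), ", amfe ",
                    round(fold$amfe, 2)))
      dropped[[length(dropped) + 1L]] <- mutate(row, reason = "structure_filter")
    }
  }
  out <- bind_rows(kept)
  if (nrow(out) == 0L) {
    out <- tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  mfe = numeric(0), amfe = numeric(0),
                  stem_length = integer(0), mismatch_fraction = numeric(0))
  }
  attr(out, "dropped") <- bind_rows(dropped)
  out
}

#' Export curated regions as BED6 plus a metrics TSV
#'
#' @param regions Curated tibble from [curate_positive_regions()].
#' @param bed_path,tsv_path Output paths.
#' @export
write_curated_regions <- function(regions, bed_path, tsv_path) {
  bed <- tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = sprintf("eer_dsrna_%d", seq_len(nrow(regions))),
    score = 0L, strand = "."
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  readr::write_tsv(regions, tsv_path)
  invisible(c(bed_path, tsv_path))
}
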