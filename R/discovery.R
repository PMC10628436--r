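#' Tile chromosomes into candidate windows and extract features
#'
#' Windows of `window` nt are tiled at a stride of `step` nt (half the
#' window by default, so covered bases fall in at most two windows). A
#' trailing partial window is kept only when strictly longer than the step.
#' Only windows passing the candidate filter (at least `min_reads`
#' overlapping reads, at least one region-skipping read) are returned, with
#' features extracted.
#'
#' @param reads Read table from [read_alignments()].
#' @param genome Named [Biostrings::DNAStringSet] (chromosome lengths).
#' @param window Window size (nt).
#' @param step Stride (nt).
#' @param min_reads Minimum overlapping reads.
#' @param min_skip_len Minimum skip length counted as region-skipping (nt).
#' @return A feature table of qualifying windows.
#' @export
enumerate_candidate_windows <- function(reads, genome, window = 2500,
                                        step = 1250, min_reads = 6,
                                        min_skip_len = 20) {
  out <- list()
  for (chrom in names(genome)) {
    len <- length(genome[[chrom]])
    starts <- if (len >= window) seq(0, len - window, by = step) else numeric(0)
    nxt <- if (length(starts) > 0) max(starts) + step else 0
    if (len - nxt > step) starts <- c(starts, nxt)
    for (s in starts) {
      e <- min(s + window, len)
      idx <- index_reads_by_window(reads, chrom, s, e,
                                   min_skip_len = min_skip_len)
      if (idx$total_reads >= min_reads && idx$skipping_reads >= 1L) {
        out[[length(out) + 1L]] <-
          extract_features(reads, genome, chrom, s, e,
                           min_skip_len = min_skip_len)
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    abort("no window passes the candidate filter")
  }
  res
}

#' Enumerate window start positions of one chromosome
#'
#' Exposed for tiling diagnostics; the same arithmetic as
#' [enumerate_candidate_windows()].
#'
#' @param len Chromosome length (nt).
#' @param window,step Window size and stride (nt).
#' @return Numeric vector of 0-based window starts.
#' @export
window_starts <- function(len, window = 2500, step = 1250) {
  starts <- if (len >= window) seq(0, len - window, by = step) else numeric(0)
  nxt <- if (length(starts) > 0) max(starts) + step else 0
  if (len - nxt > step) starts <- c(starts, nxt)
  starts
}

#' Score candidates and curate discovered dsRNA regions
#'
#' Candidates are scored by the model; windows with probability strictly
#' above `prob_threshold` are retained, any window sharing at least one
#' base with a curated positive region is excluded, and the survivors'
#' reference sequences are folded and classified into novel long dsRNAs or
#' generally structured RNAs. A folding failure on one window drops that
#' window with a message rather than aborting the scan.
#'
#' @param candidates Feature table from [enumerate_candidate_windows()].
#' @param model A `dsrna_model`.
#' @param positives Curated positive intervals (`chrom`, `start`, `end`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param engine Folding engine (default [rnafold_engine()]); ignored when
#'   `fold = FALSE`.
#' @param prob_threshold Retention threshold on predicted probability.
#' @param fold Whether to fold and classify survivors; when `FALSE` the
#'   structural columns are `NA` (useful for recall diagnostics).
#' @param min_stem,max_mismatch,amfe_max Structure thresholds (see
#'   [classify_structure()]).
#' @param max_fold_len Maximum folded sequence length (nt).
#' @return A tibble sorted by descending probability: `chrom`, `start`,
#'   `end`, `probability`, `class`, `mfe`, `amfe`, `stem_length`,
#'   `mismatch_fraction`.
#' @export
discover_dsrna <- function(candidates, model, positives, genome,
                           engine = NULL, prob_threshold = 0.5, fold = TRUE,
                           min_stem = 200, max_mismatch = 0.20,
                           amfe_max = -35.0, max_fold_len = 5000) {
  prob <- predict_proba(model, candidates)
  keep <- prob > prob_threshold
  cand <- candidates[keep, c("chrom", "start", "end")]
  cand$probability <- prob[keep]
  if (nrow(cand) > 0L) {
    ov <- vapply(seq_len(nrow(cand)), function(k) {
      overlaps_any(cand$chrom[k], cand$start[k], cand$end[k], positives)
    }, logical(1))
    cand <- cand[!ov, ]
  }
  cand$class <- NA_character_
  cand$mfe <- NA_real_; cand$amfe <- NA_real_
  cand$stem_length <- NA_integer_; cand$mismatch_fraction <- NA_real_
  if (fold && nrow(cand) > 0L) {
    if (is.null(engine)) engine <- rnafold_engine()
    ok <- rep(TRUE, nrow(cand))
    for (k in seq_len(nrow(cand))) {
      res <- tryCatch({
        seq <- ref_segment(genome, cand$chrom[k], cand$start[k], cand$end[k])
        f <- fold_sequence(seq, engine = engine, max_len = max_fold_len)
        s <- stem_report(f$dotbracket)
        list(f = f, s = s)
      }, error = function(e) {
        inform(paste0("folding failed for ", cand$chrom[k], ":",
                      cand$start[k], "-", cand$end[k], ": ",
                      conditionMessage(e)))
        NULL
      })
      if (is.null(res)) { ok[k] <- FALSE; next }
      cand$mfe[k] <- res$f$mfe; cand$amfe[k] <- res$f$amfe
      cand$stem_length[k] <- res$s$length
      cand$mismatch_fraction[k] <- res$s$mismatch_fraction
      cand$class[k] <- classify_structure(res$f, res$s, min_stem = min_stem,
                                          max_mismatch = max_mismatch,
                                          amfe_max = amfe_max)
    }
    cand <- cand[ok, ]
  }
  arrange(cand, desc(.data$probability), .data$chrom, .data$start)
}

# SAM -> sorted, indexed BAM (pass BAM through untouched if already indexed);
# conversions are cached per (path, mtime) so per-region calls reuse them
.bam_cache <- new.env(parent = emptyenv())

ensure_indexed_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    key <- paste0(normalizePath(path), "@", file.mtime(path))
    hit <- .bam_cache[[key]]
    if (!is.null(hit) && file.exists(hit)) return(hit)
    bam <- Rsamtools::asBam(path, destination = tempfile(),
                            overwrite = TRUE, indexDestination = TRUE)
    .bam_cache[[key]] <- bam
    return(bam)
  }
  if (!file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  path
}

#' A-to-I editing index of a region
#'
#' For every catalog editing site inside the region covered by more than
#' `min_coverage - 1` reads, reference-A positions read as G are tallied
#' (on the minus strand, T positions read as C); the editing index is the
#' pooled G count over the pooled A + G count. Coverage counts aligned,
#' non-deleted bases at the site.
#'
#' @param chrom,start,end Region interval, 0-based half-open.
#' @param alignments Path to a BAM or SAM file.
#' @param sites Editing-site tibble from [load_editing_sites()].
#' @param min_coverage Minimum reads covering a site for inclusion
#'   (default 4, i.e. strictly more than three).
#' @return A one-row tibble: `chrom`, `start`, `end`, `n_sites`,
#'   `a_count`, `g_count`, `editing_index` (`NA` when no site qualifies).
#' @export
compute_editing_index <- function(chrom, start, end, alignments, sites,
                                  min_coverage = 4) {
  in_region <- filter(sites, .data$chrom == !!chrom, .data$pos >= !!start,
                      .data$pos < !!end)
  empty <- tibble(chrom = chrom, start = start, end = end, n_sites = 0L,
                  a_count = 0L, g_count = 0L, editing_index = NA_real_)
  if (nrow(in_region) == 0L) return(empty)
  bam <- ensure_indexed_bam(alignments)
  which <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = in_region$pos + 1, width = 1)
  )
  pp <- Rsamtools::PileupParam(max_depth = 10000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 0L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::pileup(bam,
                         scanBamParam = Rsamtools::ScanBamParam(which = which,
                                                                flag = flags),
                         pileupParam = pp)
  a_total <- 0L; g_total <- 0L; n_used <- 0L
  for (k in seq_len(nrow(in_region))) {
    pos1 <- in_region$pos[k] + 1
    at <- p[p$pos == pos1, ]
    coverage <- sum(at$count[at$nucleotide %in% c("A", "C", "G", "T")])
    if (coverage < min_coverage) next
    if (in_region$strand[k] == "+") {
      a <- sum(at$count[at$nucleotide == "A"])
      g <- sum(at$count[at$nucleotide == "G"])
    } else {
      a <- sum(at$count[at$nucleotide == "T"])
      g <- sum(at$count[at$nucleotide == "C"])
    }
    a_total <- a_total + a; g_total <- g_total + g
    n_used <- n_used + 1L
  }
  tibble(chrom = chrom, start = start, end = end, n_sites = n_used,
         a_count = a_total, g_count = g_total,
         editing_index = if (a_total + g_total > 0) {
           g_total / (a_total + g_total)
         } else NA_real_)
}

#' Export discovered regions as BED6 and a metrics TSV
#'
#' The BED name is the structural class, the BED score
#' `round(probability * 1000)`. Output bytes are a deterministic function
#' of the input.
#'
#' @param regions Tibble from [discover_dsrna()] (sorted).
#' @param bed_path,tsv_path Output paths.
#' @export
export_results <- function(regions, bed_path, tsv_path) {
  bed <- tibble(
    chrom = regions$chrom,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE),
    name = ifelse(is.na(regions$class), "unclassified", regions$class),
    score = round(regions$probability * 1000),
    strand = rep(".", nrow(regions))
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  readr::write_tsv(regions, tsv_path)
  invisible(c(bed_path, tsv_path))
}
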