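#' Names of the per-window predictors, in canonical order
#'
#' Six summary features of internal region-skipping plus 16 + 16 boundary
#' dinucleotide frequencies (first two and last two reference bases of the
#' skipped segment), 38 in total. Dinucleotides discriminate splicing (GT...AG)
#' from stochastic template-switching, which has no boundary motif.
#'
#' @return Character vector of length 38.
#' @export
feature_names <- function() {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            function(a, b) paste0(a, b)))
  dinucs <- sort(dinucs)
  c("skip_ratio", "len_skip", "group_num", "std_start", "std_end", "gc_skip",
    paste0("bp_start_", dinucs), paste0("bp_end_", dinucs))
}

#' Skipping ratio and mean skip length of a window
#'
#' @param total_reads Reads overlapping the window.
#' @param skips Tibble of skip events in the window (`start`, `end`).
#' @param skipping_reads Number of distinct reads with at least one skip.
#' @return A list with `skip_ratio` (skipping reads / total reads) and
#'   `len_skip` (mean skipped length over events, nt).
#' @export
compute_skip_stats <- function(total_reads, skips, skipping_reads) {
  if (total_reads == 0L) abort("empty window reached feature stage")
  list(
    skip_ratio = skipping_reads / total_reads,
    len_skip = if (nrow(skips) > 0L) mean(skips$end - skips$start) else NA_real_
  )
}

# A group is valid when both extremes sit < radius from the group median.
group_valid <- function(g, radius) {
  m <- stats::median(g)
  (max(g) - m) < radius && (m - min(g)) < radius
}

# Coarsest valid contiguous partition of a sorted vector (fewest groups),
# tie-broken by greedily taking the longest first group. O(n^2) feasibility.
coarsest_partition <- function(pos, radius) {
  n <- length(pos)
  if (n == 1L) return(list(pos))
  m <- rep(Inf, n + 1L); m[n + 1L] <- 0
  for (i in n:1) {
    for (j in i:n) {
      if (group_valid(pos[i:j], radius)) m[i] <- min(m[i], 1 + m[j + 1L])
    }
  }
  out <- list(); i <- 1L
  while (i <= n) {
    j_best <- NA_integer_
    for (j in i:n) {
      if (group_valid(pos[i:j], radius) && 1 + m[j + 1L] == m[i]) j_best <- j
    }
    out[[length(out) + 1L]] <- pos[i:j_best]
    i <- j_best + 1L
  }
  out
}

#' Group skip boundary coordinates
#'
#' Skip starts (or ends) from different reads of the same event cloud are
#' clustered: coordinates within `radius` of each other are linked into a
#' cluster, and each cluster is then partitioned into the fewest groups such
#' that every group's leftmost and rightmost coordinates lie strictly within
#' `radius` of the group median.
#'
#' @param positions Numeric vector of genomic coordinates (any order).
#' @param radius Linkage and median-deviation radius (nt).
#' @return A list of sorted numeric vectors partitioning `positions`.
#' @export
#' @examples
#' group_positions(c(100, 150, 420))
group_positions <- function(positions, radius = 100) {
  if (length(positions) == 0L) abort("group_positions: empty input")
  pos <- sort(positions)
  gaps <- diff(pos)
  clusters <- unname(split(pos, cumsum(c(0, gaps > radius))))
  out <- unlist(lapply(clusters, coarsest_partition, radius = radius),
                recursive = FALSE)
  unname(out)
}

# population standard deviation (divisor n): stable for singletons
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarise start- and end-boundary groups
#'
#' @param start_groups,end_groups Lists of coordinate vectors from
#'   [group_positions()] applied to skip starts and skip ends.
#' @return A list: `group_num` (mean of the two group counts, may be a
#'   half-integer), `std_start` and `std_end` (mean per-group population
#'   standard deviation, nt).
#' @export
group_summary <- function(start_groups, end_groups) {
  stopifnot(length(start_groups) > 0L, length(end_groups) > 0L)
  list(
    group_num = (length(start_groups) + length(end_groups)) / 2,
    std_start = mean(vapply(start_groups, pop_sd, numeric(1))),
    std_end = mean(vapply(end_groups, pop_sd, numeric(1)))
  )
}

# Genome access: named DNAStringSet. Returns uppercase character sequence.
ref_segment <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    abort(paste0("reference chromosome missing: ", chrom))
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len) {
    abort(paste0("interval [", start, ",", end, ") outside ", chrom,
                 " (length ", len, ")"))
  }
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start + 1, end)))
}

#' Sequence composition of skipped segments
#'
#' GC content of the skipped reference segment averaged over events, and
#' frequencies of the boundary dinucleotides: the first two and last two
#' reference bases of each skipped segment. Events with an ambiguous base
#' (N) in a boundary dinucleotide are excluded from that side's denominator.
#'
#' @param skips Tibble of skip events (`chrom`, `start`, `end`).
#' @param genome Named [Biostrings::DNAStringSet] of reference sequences.
#' @return A list: `gc_skip`, and named frequency vectors `bp_start`,
#'   `bp_end` (16 elements each).
#' @export
skipped_segment_composition <- function(skips, genome) {
  dinucs <- sort(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0)))
  zero <- setNames(rep(0, 16), dinucs)
  if (nrow(skips) == 0L) {
    return(list(gc_skip = NA_real_, bp_start = zero, bp_end = zero))
  }
  stopifnot(all(skips$end - skips$start >= 2))
  seqs <- pmap(list(skips$chrom, skips$start, skips$end),
               function(c, s, e) ref_segment(genome, c, s, e))
  gc <- map_dbl(seqs, function(s) {
    bases <- strsplit(s, "")[[1]]
    mean(bases %in% c("G", "C"))
  })
  d_start <- map_chr(seqs, ~ substr(.x, 1, 2))
  d_end <- map_chr(seqs, ~ substr(.x, nchar(.x) - 1, nchar(.x)))
  freq <- function(d) {
    d <- d[d %in% dinucs]
    if (length(d) == 0L) return(zero)
    tab <- table(factor(d, levels = dinucs))
    setNames(as.numeric(tab) / length(d), dinucs)
  }
  list(gc_skip = mean(gc), bp_start = freq(d_start), bp_end = freq(d_end))
}

#' Extract the full feature vector of one window
#'
#' Assembles the 38 predictors of a candidate window from its overlapping
#' reads, their skip events and the reference sequence.
#'
#' @param reads Read table from [read_alignments()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param chrom,start,end Window interval, 0-based half-open.
#' @param min_skip_len Minimum skip length (nt) counted as region-skipping.
#' @param radius Grouping radius (nt) for boundary clustering.
#' @return A one-row tibble with columns `chrom`, `start`, `end`,
#'   `total_reads`, `skipping_reads` and the 38 features of
#'   [feature_names()].
#' @export
extract_features <- function(reads, genome, chrom, start, end,
                             min_skip_len = 20, radius = 100) {
  idx <- index_reads_by_window(reads, chrom, start, end,
                               min_skip_len = min_skip_len)
  stats <- compute_skip_stats(idx$total_reads, idx$skips, idx$skipping_reads)
  if (nrow(idx$skips) == 0L) {
    abort("window has no qualifying skip events; candidate filter not applied?")
  }
  grp <- group_summary(group_positions(idx$skips$start, radius),
                       group_positions(idx$skips$end, radius))
  comp <- skipped_segment_composition(idx$skips, genome)
  out <- tibble(
    chrom = chrom, start = start, end = end,
    total_reads = idx$total_reads, skipping_reads = idx$skipping_reads,
    skip_ratio = stats$skip_ratio, len_skip = stats$len_skip,
    group_num = grp$group_num, std_start = grp$std_start,
    std_end = grp$std_end, gc_skip = comp$gc_skip
  )
  for (d in names(comp$bp_start)) out[[paste0("bp_start_", d)]] <- comp$bp_start[[d]]
  for (d in names(comp$bp_end)) out[[paste0("bp_end_", d)]] <- comp$bp_end[[d]]
  out[, c("chrom", "start", "end", "total_reads", "skipping_reads",
          feature_names())]
}

#' Extract features for many windows
#'
#' @param windows Tibble with `chrom`, `start`, `end`.
#' @inheritParams extract_features
#' @return Row-bound feature table, one row per window.
#' @export
extract_feature_table <- function(windows, reads, genome,
                                  min_skip_len = 20, radius = 100) {
  if (nrow(windows) == 0L) {
    abort("no windows supplied")
  }
  bind_rows(pmap(
    list(windows$chrom, windows$start, windows$end),
    function(c, s, e) extract_features(reads, genome, c, s, e,
                                       min_skip_len = min_skip_len,
                                       radius = radius)
  ))
}

#' Write / read a feature table as TSV
#'
#' Round-trips bit-exactly: numbers are written with full precision.
#'
#' @param features Feature table from [extract_feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  for (nm in setdiff(names(tbl), "chrom")) {
    tbl[[nm]] <- as.numeric(tbl[[nm]])
  }
  for (nm in intersect(c("total_reads", "skipping_reads", "label"),
                       names(tbl))) {
    tbl[[nm]] <- as.integer(tbl[[nm]])
  }
  tbl
}
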