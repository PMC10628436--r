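#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr filter mutate arrange select group_by summarise ungroup
#'   distinct bind_rows n left_join across all_of row_number desc
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 map_int map_dbl map_chr pmap imap keep
#' @importFrom stats median rnorm rpois runif rbinom rbeta sd setNames predict
#' @importFrom utils head tail
NULL

# SAM flag bits
.FLAG_UNMAPPED      <- 0x4L
.FLAG_SECONDARY     <- 0x100L
.FLAG_SUPPLEMENTARY <- 0x800L

#' Extract internal skip events from one alignment record
#'
#' An internal skip is a stretch of reference sequence absent from the read's
#' alignment: an `N` operation in the CIGAR, or equivalently a `~` item in
#' minimap2's `cs` difference string. Real introns and reverse-transcriptase
#' template-switching artifacts both present this way; downstream features
#' tell the two apart.
#'
#' When a `cs` tag is available it takes precedence over the CIGAR; the two
#' encodings of the same alignment yield identical events.
#'
#' @param cigar CIGAR string of the record.
#' @param pos 0-based leftmost reference position of the alignment.
#' @param chrom Chromosome name.
#' @param read_id Read name.
#' @param cs Optional `cs` tag value (short form, e.g. `":50~gt120ag:30"`).
#' @param flag SAM flag; unmapped records are rejected.
#'
#' @return A tibble with one row per skip event: `read_id`, `chrom`, `start`,
#'   `end` (0-based half-open genomic span of the skipped segment) and
#'   `length`. Zero rows when the record has no internal skipping.
#' @export
#' @examples
#' parse_skip_events("50M120N30M", pos = 1000, chrom = "chr1", read_id = "r1")
parse_skip_events <- function(cigar, pos, chrom = "chr", read_id = "read",
                              cs = NULL, flag = 0L) {
  if (bitwAnd(as.integer(flag), .FLAG_UNMAPPED) != 0L) {
    abort("unmapped record: skip events are undefined")
  }
  if (!is.null(cs) && !is.na(cs) && nzchar(cs)) {
    ev <- cs_skip_spans(cs, pos)
  } else {
    ev <- cigar_skip_spans(cigar, pos)
  }
  n_ev <- length(ev$start)
  tibble(
    read_id = rep(read_id, n_ev),
    chrom = rep(chrom, n_ev),
    start = ev$start, end = ev$end,
    length = ev$end - ev$start
  )
}

# Walk a short-form cs string tracking reference consumption.
# Items: ":<n>" match, "*<ref><alt>" substitution (1 ref nt), "+<seq>"
# insertion (0 ref nt), "-<seq>" deletion (len ref nt),
# "~<dn2><len><ac2>" reference skip, "=<seq>" exact match (long form).
cs_skip_spans <- function(cs, pos) {
  ref <- as.numeric(pos)
  starts <- numeric(0); ends <- numeric(0)
  i <- 1L; n <- nchar(cs)
  while (i <= n) {
    op <- substr(cs, i, i)
    rest <- substr(cs, i + 1L, n)
    if (op == ":") {
      m <- regmatches(rest, regexpr("^[0-9]+", rest))
      if (length(m) == 0L) abort(paste0("malformed cs tag at ':", substr(rest, 1, 8), "'"))
      ref <- ref + as.numeric(m)
      i <- i + 1L + nchar(m)
    } else if (op == "*") {
      m <- regmatches(rest, regexpr("^[acgtn][acgtn]", rest))
      if (length(m) == 0L) abort(paste0("malformed cs tag at '*", substr(rest, 1, 8), "'"))
      ref <- ref + 1
      i <- i + 3L
    } else if (op == "+" || op == "-" || op == "=") {
      m <- regmatches(rest, regexpr("^[A-Za-z]+", rest))
      if (length(m) == 0L) abort(paste0("malformed cs tag at '", op, substr(rest, 1, 8), "'"))
      if (op == "-") ref <- ref + nchar(m)
      if (op == "=") ref <- ref + nchar(m)
      i <- i + 1L + nchar(m)
    } else if (op == "~") {
      m <- regmatches(rest, regexpr("^[acgtn]{2}[0-9]+[acgtn]{2}", rest))
      if (length(m) == 0L) abort(paste0("malformed cs tag at '~", substr(rest, 1, 8), "'"))
      len <- as.numeric(gsub("[acgtn]", "", m))
      starts <- c(starts, ref); ends <- c(ends, ref + len)
      ref <- ref + len
      i <- i + 1L + nchar(m)
    } else {
      abort(paste0("malformed cs tag: unexpected token '", op, "' at offset ", i))
    }
  }
  list(start = starts, end = ends)
}

# CIGAR reference-consuming ops: M, =, X, D, N; N runs are skips.
cigar_ops <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*") {
    return(list(len = numeric(0), op = character(0)))
  }
  lens <- as.numeric(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) abort(paste0("malformed CIGAR '", cigar, "'"))
  list(len = lens, op = ops)
}

cigar_skip_spans <- function(cigar, pos) {
  co <- cigar_ops(cigar)
  ref <- as.numeric(pos)
  starts <- numeric(0); ends <- numeric(0)
  for (k in seq_along(co$op)) {
    op <- co$op[k]; len <- co$len[k]
    if (op == "N") {
      starts <- c(starts, ref); ends <- c(ends, ref + len)
    }
    if (op %in% c("M", "=", "X", "D", "N")) ref <- ref + len
  }
  list(start = starts, end = ends)
}

#' Reference span consumed by a CIGAR string
#' @param cigar CIGAR string.
#' @return Number of reference bases consumed (M/=/X/D/N operations).
#' @export
cigar_reference_span <- function(cigar) {
  co <- cigar_ops(cigar)
  sum(co$len[co$op %in% c("M", "=", "X", "D", "N")])
}

#' Read spliced long-read alignments into a tidy table
#'
#' Loads primary, mapped alignments from a BAM or SAM file (SAM input is
#' converted on the fly) and extracts internal skip events from the `cs` tag
#' when present, falling back to CIGAR `N` operations. Secondary,
#' supplementary and unmapped records are dropped: one molecule, one vote.
#'
#' @param path Path to a coordinate-sorted BAM or SAM file.
#' @return A tibble with one row per read: `read_id`, `chrom`, `aln_start`,
#'   `aln_end` (0-based half-open alignment span) and `skips`, a list-column
#'   of per-read skip-event tibbles (`start`, `end`, `length`).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "cs", flag = flags
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  cs <- rec$tag$cs %||% rep(NA_character_, length(rec$qname))
  if (length(cs) == 0L) cs <- rep(NA_character_, length(rec$qname))
  reads <- tibble(
    read_id = rec$qname,
    chrom = as.character(rec$rname),
    aln_start = as.numeric(rec$pos) - 1,
    cigar = rec$cigar,
    cs = as.character(cs)
  )
  reads |>
    mutate(
      aln_end = .data$aln_start + map_dbl(.data$cigar, cigar_reference_span),
      skips = pmap(
        list(.data$cigar, .data$aln_start, .data$chrom, .data$read_id, .data$cs),
        function(cigar, pos, chrom, read_id, cs) {
          parse_skip_events(cigar, pos, chrom = chrom, read_id = read_id,
                            cs = if (is.na(cs)) NULL else cs)[, c("start", "end", "length")]
        }
      )
    ) |>
    select("read_id", "chrom", "aln_start", "aln_end", "skips") |>
    arrange(.data$chrom, .data$aln_start, .data$read_id)
}

#' Flatten per-read skip events
#'
#' @param reads Read table from [read_alignments()].
#' @return A tibble of all skip events with `read_id`, `chrom`, `start`,
#'   `end`, `length`.
#' @export
skip_events <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0), length = numeric(0)))
  }
  reads |>
    select("read_id", "chrom", "skips") |>
    tidyr::unnest("skips")
}

#' Count reads and skip events in a genomic window
#'
#' A read belongs to the window when its alignment span overlaps it by at
#' least one nucleotide. A skip event belongs to the window when its start
#' coordinate falls inside the window, giving every event a single,
#' unambiguous window even when it straddles a boundary. Skips shorter than
#' `min_skip_len` are treated as small deletions, not region-skipping.
#'
#' @param reads Read table from [read_alignments()] (same chromosome as the
#'   window, or a superset; other chromosomes are ignored).
#' @param chrom,start,end Window interval, 0-based half-open.
#' @param min_skip_len Minimum skip length (nt) to count as region-skipping.
#' @return A list: `total_reads`, `skipping_reads`, and `skips` (a tibble of
#'   qualifying events). A read with several qualifying skips counts once in
#'   `skipping_reads` but contributes every event.
#' @export
index_reads_by_window <- function(reads, chrom, start, end, min_skip_len = 20) {
  stopifnot(end > start)
  if (nrow(reads) == 0L) {
    return(list(total_reads = 0L, skipping_reads = 0L,
                skips = skip_events(reads)))
  }
  overlapping <- reads |>
    filter(.data$chrom == !!chrom, .data$aln_start < !!end, .data$aln_end > !!start)
  ev <- skip_events(overlapping) |>
    filter(.data$length >= !!min_skip_len,
           .data$start >= !!start, .data$start < !!end)
  list(
    total_reads = nrow(overlapping),
    skipping_reads = dplyr::n_distinct(ev$read_id),
    skips = ev
  )
}

#' Load an A-to-I editing-site catalog
#'
#' Reads a REDIportal-style tab-separated catalog of editing sites. Column
#' positions are configurable; positions are converted from 1-based to the
#' package's 0-based convention, duplicates removed, and sites sorted within
#' chromosome.
#'
#' @param path Path to a TSV file.
#' @param chrom_col,pos_col,strand_col 1-based column indices of chromosome,
#'   position and strand.
#' @param one_based Whether file positions are 1-based (default `TRUE`).
#' @return A tibble with `chrom`, `pos` (0-based), `strand`, sorted by
#'   chromosome then position.
#' @export
load_editing_sites <- function(path, chrom_col = 1L, pos_col = 2L,
                               strand_col = 3L, one_based = TRUE) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(0), pos = numeric(0), strand = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- max(chrom_col, pos_col, strand_col)
  first <- fields[[1]]
  # header row: first record's position field is non-numeric
  if (length(first) >= need && is.na(suppressWarnings(as.numeric(first[pos_col])))) {
    fields <- fields[-1]
    lines <- lines[-1]
  }
  if (length(fields) == 0L) {
    return(tibble(chrom = character(0), pos = numeric(0), strand = character(0)))
  }
  rows <- imap(fields, function(f, i) {
    if (length(f) < need) {
      abort(paste0("unparseable editing-catalog line ", i, ": '", lines[i], "'"))
    }
    pos <- suppressWarnings(as.numeric(f[pos_col]))
    if (is.na(pos)) {
      abort(paste0("unparseable position on editing-catalog line ", i,
                   ": '", f[pos_col], "'"))
    }
    strand <- f[strand_col]
    if (!strand %in% c("+", "-")) {
      abort(paste0("unknown strand symbol '", strand,
                   "' on editing-catalog line ", i))
    }
    tibble(chrom = f[chrom_col], pos = pos, strand = strand)
  })
  bind_rows(rows) |>
    mutate(pos = .data$pos - as.numeric(one_based)) |>
    distinct(.data$chrom, .data$pos, .data$strand) |>
    arrange(.data$chrom, .data$pos, .data$strand)
}
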