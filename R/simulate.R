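#' Configuration of the synthetic corpus generator
#'
#' The generator plants three kinds of loci in a random background genome:
#' dsRNA loci (an inverted repeat: arm, loop, reverse-complemented arm) whose
#' reads skip the hairpin at a low per-read frequency with jittered,
#' motif-free boundaries; splice loci with fixed GT--AG junctions skipped at
#' a bimodally distributed per-locus inclusion level; and untouched
#' background. dsRNA loci additionally receive clustered A-to-I editing
#' sites within their arms, realised as A-to-G substitutions in a matching
#' fraction of read bases.
#'
#' Defaults emulate deeply covered long-read data at desk scale: mean
#' coverage 20 reads per locus (comfortably above the six-read candidate
#' floor), hairpin skip fractions of 0.02--0.2 against bimodal Beta(0.3,
#' 0.3) splice inclusion, and 30-nt boundary jitter for template-switching
#' skips.
#'
#' @param genome_length Background genome length (nt).
#' @param n_dsrna_loci,n_splice_loci,n_noise_loci Number of planted loci of
#'   each kind.
#' @param arm_length_range Hairpin arm length range (nt).
#' @param loop_range Hairpin loop length range (nt).
#' @param skip_fraction_range Per-locus hairpin skip probability range.
#' @param jitter_sd Standard deviation of skip boundary jitter (nt).
#' @param inclusion_shape Beta shape parameters of per-locus splice
#'   inclusion (both shared), giving a bimodal distribution.
#' @param mean_coverage Mean reads per locus (Poisson).
#' @param read_length_range Aligned read span range (nt).
#' @param intron_length_range Splice intron length range (nt).
#' @param exon_length Flanking exon length of splice loci (nt).
#' @param editing_sites_range Editing sites planted per dsRNA locus.
#' @param editing_level_range Per-site editing level range.
#' @param noise_skip_fraction_range Per-read skip probability range of noise
#'   loci.
#' @param noise_skip_length_range Skipped-segment length range of noise loci
#'   (nt).
#' @param locus_spacing Minimum gap between planted loci (nt).
#' @param seed Integer seed; every downstream artifact is deterministic in
#'   it.
#' @return A named list of class `sim_config`.
#' @export
simulation_config <- function(genome_length = 1500000,
                              n_dsrna_loci = 100, n_splice_loci = 100,
                              n_noise_loci = 100,
                              arm_length_range = c(200, 600),
                              loop_range = c(50, 500),
                              skip_fraction_range = c(0.02, 0.2),
                              jitter_sd = 30,
                              inclusion_shape = 0.3,
                              mean_coverage = 20,
                              read_length_range = c(2000, 3200),
                              intron_length_range = c(300, 1500),
                              exon_length = 300,
                              editing_sites_range = c(10, 30),
                              editing_level_range = c(0.1, 0.5),
                              noise_skip_fraction_range = c(0.3, 0.9),
                              noise_skip_length_range = c(100, 800),
                              locus_spacing = 2500,
                              seed = 1L) {
  stopifnot(mean_coverage >= 6,
            arm_length_range[2] >= arm_length_range[1],
            loop_range[2] >= loop_range[1],
            skip_fraction_range[2] > skip_fraction_range[1])
  structure(
    list(genome_length = genome_length, n_dsrna_loci = n_dsrna_loci,
         n_splice_loci = n_splice_loci, n_noise_loci = n_noise_loci,
         arm_length_range = arm_length_range,
         loop_range = loop_range, skip_fraction_range = skip_fraction_range,
         jitter_sd = jitter_sd, inclusion_shape = inclusion_shape,
         mean_coverage = mean_coverage,
         read_length_range = read_length_range,
         intron_length_range = intron_length_range,
         exon_length = exon_length,
         editing_sites_range = editing_sites_range,
         editing_level_range = editing_level_range,
         noise_skip_fraction_range = noise_skip_fraction_range,
         noise_skip_length_range = noise_skip_length_range,
         locus_spacing = locus_spacing, seed = as.integer(seed)),
    class = "sim_config"
  )
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

runif_int <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

#' Simulate a genome with planted dsRNA hairpins and splice loci
#'
#' @param config A [simulation_config()].
#' @return A list: `genome` (a named [Biostrings::DNAStringSet] with one
#'   chromosome `"sim1"`) and `truth`, a tibble of planted loci with
#'   `chrom`, `start`, `end`, `kind` (`"dsRNA"`, `"splice"` or `"noise"`),
#'   `arm_length`, `loop_length`, `skip_fraction`, `event_start`,
#'   `event_end` (`NA` where not applicable; for splice loci the intron, for
#'   noise loci the fixed skipped segment).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chrom <- "sim1"
  n_loci <- config$n_dsrna_loci + config$n_splice_loci + config$n_noise_loci
  kinds <- sample(c(rep("dsRNA", config$n_dsrna_loci),
                    rep("splice", config$n_splice_loci),
                    rep("noise", config$n_noise_loci)))
  # draw locus payloads first so total footprint is known
  loci <- map(kinds, function(kind) {
    if (kind == "dsRNA") {
      arm <- runif_int(1, config$arm_length_range)
      loop <- runif_int(1, config$loop_range)
      arm_seq <- rand_seq(arm)
      list(kind = kind, seq = paste0(arm_seq, rand_seq(loop), revcomp(arm_seq)),
           arm = arm, loop = loop,
           skip_fraction = runif(1, config$skip_fraction_range[1],
                                 config$skip_fraction_range[2]))
    } else if (kind == "splice") {
      intron <- runif_int(1, config$intron_length_range)
      iseq <- rand_seq(intron)
      substr(iseq, 1, 2) <- "GT"
      substr(iseq, intron - 1, intron) <- "AG"
      list(kind = kind,
           seq = paste0(rand_seq(config$exon_length), iseq,
                        rand_seq(config$exon_length)),
           intron = intron)
    } else {
      noise_len <- runif_int(1, config$noise_skip_length_range)
      list(kind = kind, seq = rand_seq(noise_len + 400), noise_len = noise_len,
           skip_fraction = runif(1, config$noise_skip_fraction_range[1],
                                 config$noise_skip_fraction_range[2]))
    }
  })
  footprint <- sum(map_int(loci, ~ nchar(.x$seq))) +
    (n_loci + 1) * config$locus_spacing
  if (footprint > config$genome_length) {
    abort(paste0("loci do not fit: need ", footprint, " nt, genome is ",
                 config$genome_length))
  }
  slack <- config$genome_length - footprint
  # distribute the slack randomly over the n_loci + 1 gaps
  extra <- if (slack > 0) {
    tabulate(sample.int(n_loci + 1L, slack, replace = TRUE), n_loci + 1L)
  } else rep(0L, n_loci + 1L)
  seq_parts <- character(0)
  truth <- list()
  cursor <- 0
  for (k in seq_len(n_loci)) {
    gap <- config$locus_spacing + extra[k]
    seq_parts <- c(seq_parts, rand_seq(gap))
    cursor <- cursor + gap
    l <- loci[[k]]
    start <- cursor
    end <- cursor + nchar(l$seq)
    seq_parts <- c(seq_parts, l$seq)
    cursor <- end
    truth[[k]] <- if (l$kind == "dsRNA") {
      tibble(chrom = chrom, start = start, end = end, kind = "dsRNA",
             arm_length = l$arm, loop_length = l$loop,
             skip_fraction = l$skip_fraction,
             event_start = NA_real_, event_end = NA_real_)
    } else if (l$kind == "splice") {
      tibble(chrom = chrom, start = start, end = end, kind = "splice",
             arm_length = NA_integer_, loop_length = NA_integer_,
             skip_fraction = NA_real_,
             event_start = start + config$exon_length,
             event_end = end - config$exon_length)
    } else {
      tibble(chrom = chrom, start = start, end = end, kind = "noise",
             arm_length = NA_integer_, loop_length = NA_integer_,
             skip_fraction = l$skip_fraction,
             event_start = start + 200, event_end = start + 200 + l$noise_len)
    }
  }
  seq_parts <- c(seq_parts, rand_seq(config$locus_spacing + extra[n_loci + 1L]))
  full <- paste(seq_parts, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(full, chrom))
  list(genome = genome, truth = bind_rows(truth))
}

#' Plant clustered editing sites in dsRNA arms
#'
#' Each dsRNA locus receives editing sites at adenosine positions within its
#' arms, placed so that at least one triple of sites falls within 50 nt
#' (the density an editing-enriched-region scan requires). Per-site editing
#' levels are drawn from the configured range and later realised as A-to-G
#' substitutions in simulated reads.
#'
#' @param genome,truth From [simulate_genome()].
#' @param config The same [simulation_config()].
#' @return A tibble: `chrom`, `pos` (0-based), `strand`, `level`, `locus`
#'   (row index into `truth`).
#' @export
simulate_editing_sites <- function(genome, truth, config) {
  set.seed(config$seed + 1L)
  # A-to-I editing decorates both strands of the duplex, so each arm gets a
  # dense triple plus its share of the remaining sites
  pick_in_arm <- function(a_pos, n_want) {
    if (length(a_pos) == 0L) return(numeric(0))
    dense_anchor <- a_pos[vapply(a_pos, function(p) {
      sum(a_pos > p & a_pos <= p + 45) >= 2
    }, logical(1))]
    picked <- if (length(dense_anchor) > 0) {
      p0 <- if (length(dense_anchor) == 1L) dense_anchor else sample(dense_anchor, 1)
      near <- a_pos[a_pos > p0 & a_pos <= p0 + 45]
      c(p0, sample(near, min(2, length(near))))
    } else {
      sample(a_pos, min(3, length(a_pos)))
    }
    rest <- setdiff(a_pos, picked)
    n_more <- min(max(0, n_want - length(picked)), length(rest))
    if (n_more > 0) picked <- c(picked, sample(rest, n_more))
    picked
  }
  out <- list()
  for (k in seq_len(nrow(truth))) {
    if (truth$kind[k] != "dsRNA") next
    arm <- truth$arm_length[k]
    bases <- strsplit(ref_segment(genome, truth$chrom[k], truth$start[k],
                                  truth$end[k]), "")[[1]]
    arm1 <- seq(truth$start[k], truth$start[k] + arm - 1)
    arm2 <- seq(truth$end[k] - arm, truth$end[k] - 1)
    a1 <- arm1[bases[arm1 - truth$start[k] + 1] == "A"]
    a2 <- arm2[bases[arm2 - truth$start[k] + 1] == "A"]
    n_sites <- runif_int(1, config$editing_sites_range)
    if (length(a1) + length(a2) < 3) {
      warn(paste0("locus ", k, " lacks adenosines for editing sites"))
      next
    }
    picked <- c(pick_in_arm(a1, ceiling(n_sites / 2)),
                pick_in_arm(a2, floor(n_sites / 2)))
    if (length(picked) < n_sites) {
      warn(paste0("locus ", k, ": planted ", length(picked),
                  " of ", n_sites, " requested editing sites"))
    }
    out[[length(out) + 1L]] <- tibble(
      chrom = truth$chrom[k], pos = sort(picked), strand = "+",
      level = runif(length(picked), config$editing_level_range[1],
                    config$editing_level_range[2]),
      locus = k
    )
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(chrom = character(0), pos = numeric(0),
                  strand = character(0), level = numeric(0),
                  locus = integer(0))
  }
  res
}

# cs tag for one read: match runs, *ag substitutions at edited positions,
# ~xxNyy at the skip (motif bases = actual reference dinucleotides)
build_cs <- function(ref_bases, read_start, read_end, skip, edits) {
  pos <- edits; type <- rep("edit", length(edits))
  if (!is.null(skip)) {
    pos <- c(pos, skip[1]); type <- c(type, "skip")
  }
  o <- order(pos)
  pos <- pos[o]; type <- type[o]
  items <- character(0)
  cursor <- read_start
  for (k in seq_along(pos)) {
    if (pos[k] > cursor) items <- c(items, paste0(":", pos[k] - cursor))
    if (type[k] == "edit") {
      items <- c(items, "*ag")
      cursor <- pos[k] + 1
    } else {
      donor <- tolower(paste(ref_bases[(skip[1]:(skip[1] + 1)) - read_start + 1],
                             collapse = ""))
      accept <- tolower(paste(ref_bases[((skip[2] - 2):(skip[2] - 1)) - read_start + 1],
                              collapse = ""))
      items <- c(items, paste0("~", donor, skip[2] - skip[1], accept))
      cursor <- skip[2]
    }
  }
  if (read_end > cursor) items <- c(items, paste0(":", read_end - cursor))
  paste(items, collapse = "")
}

#' Simulate spliced long-read alignments over planted loci
#'
#' Per locus, coverage is Poisson with the configured mean. Reads at dsRNA
#' loci independently skip the hairpin with the locus skip fraction, with
#' normally jittered boundaries and no sequence motif; reads at splice loci
#' skip the intron exactly at its GT/AG junctions with the locus inclusion
#' probability (a Beta draw). Editing sites are realised as A-to-G
#' substitutions in a per-site fraction of covering reads. Records carry
#' both a CIGAR (with `N` runs) and a consistent `cs` tag.
#'
#' @param genome,truth From [simulate_genome()].
#' @param config The same [simulation_config()].
#' @param sites Optional editing-site tibble from
#'   [simulate_editing_sites()]; when supplied, read sequences carry the
#'   planted substitutions.
#' @return A tibble of alignment records sorted by position: `read_id`,
#'   `chrom`, `pos` (0-based), `cigar`, `cs`, `seq`, plus the locus index
#'   and a `skipped` flag.
#' @export
simulate_alignments <- function(genome, truth, config, sites = NULL) {
  set.seed(config$seed + 2L)
  chrom_len <- length(genome[[1]])
  chrom <- names(genome)[1]
  genome_chars <- strsplit(as.character(genome[[1]]), "")[[1]]
  v_pos <- numeric(0); v_cigar <- character(0); v_cs <- character(0)
  v_seq <- character(0); v_locus <- integer(0); v_skipped <- logical(0)
  for (k in seq_len(nrow(truth))) {
    n_reads <- rpois(1, config$mean_coverage)
    if (n_reads == 0L) next
    span <- truth$end[k] - truth$start[k]
    inclusion <- if (truth$kind[k] == "splice") {
      rbeta(1, config$inclusion_shape, config$inclusion_shape)
    } else NA_real_
    loc_sites <- if (!is.null(sites) && nrow(sites) > 0) {
      filter(sites, .data$locus == k)
    } else NULL
    for (r in seq_len(n_reads)) {
      len <- max(runif_int(1, config$read_length_range), span + 100)
      slack <- len - span
      rs <- truth$start[k] - runif_int(1, c(0, slack))
      rs <- max(0, min(rs, chrom_len - len))
      re <- rs + len
      skip <- NULL
      if (truth$kind[k] == "dsRNA") {
        if (runif(1) < truth$skip_fraction[k]) {
          for (try in 1:50) {
            s0 <- round(rnorm(1, truth$start[k], config$jitter_sd))
            s1 <- round(rnorm(1, truth$end[k], config$jitter_sd))
            if (s0 > rs + 2 && s1 < re - 2 && s1 - s0 >= 20) {
              skip <- c(s0, s1); break
            }
          }
        }
      } else if (truth$kind[k] == "splice") {
        if (runif(1) < inclusion) {
          skip <- c(truth$event_start[k], truth$event_end[k])
        }
      } else {
        if (runif(1) < truth$skip_fraction[k]) {
          skip <- c(truth$event_start[k], truth$event_end[k])
        }
      }
      ref_bases <- genome_chars[(rs + 1):re]
      edits <- numeric(0)
      if (!is.null(loc_sites) && nrow(loc_sites) > 0) {
        covered <- loc_sites$pos >= rs & loc_sites$pos < re
        if (!is.null(skip)) {
          covered <- covered & !(loc_sites$pos >= skip[1] & loc_sites$pos < skip[2])
        }
        cand <- loc_sites[covered, ]
        if (nrow(cand) > 0) {
          hit <- runif(nrow(cand)) < cand$level
          edits <- sort(cand$pos[hit])
        }
      }
      read_bases <- ref_bases
      if (length(edits) > 0) read_bases[edits - rs + 1] <- "G"
      if (!is.null(skip)) {
        keep <- c(seq_len(skip[1] - rs), (skip[2] - rs + 1):len)
        seq_str <- paste(read_bases[keep], collapse = "")
        cigar <- paste0(skip[1] - rs, "M", skip[2] - skip[1], "N",
                        re - skip[2], "M")
      } else {
        seq_str <- paste(read_bases, collapse = "")
        cigar <- paste0(len, "M")
      }
      cs <- build_cs(ref_bases, rs, re, skip, edits)
      v_pos <- c(v_pos, rs); v_cigar <- c(v_cigar, cigar)
      v_cs <- c(v_cs, cs); v_seq <- c(v_seq, seq_str)
      v_locus <- c(v_locus, k); v_skipped <- c(v_skipped, !is.null(skip))
    }
  }
  aln <- tibble(read_id = "", chrom = chrom, pos = v_pos, cigar = v_cigar,
                cs = v_cs, seq = v_seq, locus = v_locus,
                skipped = v_skipped) |>
    arrange(.data$pos)
  aln$read_id <- sprintf("read_%06d", seq_len(nrow(aln)))
  aln
}

#' Write simulated alignments as a coordinate-sorted SAM file
#'
#' @param aln Alignment tibble from [simulate_alignments()].
#' @param genome The genome the alignments refer to.
#' @param path Output SAM path.
#' @export
write_sam <- function(aln, genome, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", names(genome), "\tLN:", Biostrings::width(genome))
  )
  body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tcs:Z:%s",
                  aln$read_id, aln$chrom, aln$pos + 1L, aln$cigar,
                  aln$seq, aln$cs)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Convert a simulated alignment table to the tidy read table
#'
#' Equivalent to writing a SAM file and re-reading it with
#' [read_alignments()], without the file round trip.
#'
#' @param aln Alignment tibble from [simulate_alignments()].
#' @return A read table as produced by [read_alignments()].
#' @export
as_read_table <- function(aln) {
  aln |>
    mutate(
      aln_start = .data$pos,
      aln_end = .data$pos + map_dbl(.data$cigar, cigar_reference_span),
      skips = pmap(list(.data$cigar, .data$pos, .data$chrom, .data$read_id,
                        .data$cs),
                   function(cigar, pos, chrom, read_id, cs) {
                     parse_skip_events(cigar, pos, chrom = chrom,
                                       read_id = read_id,
                                       cs = cs)[, c("start", "end", "length")]
                   })
    ) |>
    select("read_id", "chrom", "aln_start", "aln_end", "skips") |>
    arrange(.data$chrom, .data$aln_start, .data$read_id)
}

#' Write an editing-site catalog as a 1-based TSV
#'
#' @param sites Site tibble (`chrom`, `pos` 0-based, `strand`).
#' @param path Output path.
#' @export
write_editing_sites <- function(sites, path) {
  readr::write_tsv(
    tibble(chrom = sites$chrom, pos = sites$pos + 1, strand = sites$strand),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Generate and write a complete synthetic corpus
#'
#' Writes `genome.fa`, `alignments.sam`, `truth.tsv`, `editing_sites.tsv`
#' and `manifest.json` (config + seed) into `dir`. Byte-identical across
#' reruns with the same config.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory `genome`, `truth`, `sites`,
#'   `alignments` and the file `paths`.
#' @export
simulate_corpus <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  sites <- simulate_editing_sites(sim$genome, sim$truth, config)
  aln <- simulate_alignments(sim$genome, sim$truth, config, sites = sites)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    alignments = file.path(dir, "alignments.sam"),
    truth = file.path(dir, "truth.tsv"),
    sites = file.path(dir, "editing_sites.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_sam(aln, sim$genome, paths$alignments)
  readr::write_tsv(sim$truth, paths$truth)
  write_editing_sites(sites, paths$sites)
  jsonlite::write_json(unclass(config), paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(genome = sim$genome, truth = sim$truth, sites = sites,
                 alignments = aln, paths = paths))
}
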