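# Shared synthetic corpora, generated once per test run and memoised.
# Small corpora keep unit tests fast; the full default configuration is used
# only where a test is explicitly about corpus-scale behaviour.

.corpus_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed, n_dsrna = 8, n_splice = 8, n_noise = 8,
                             genome_length = 140000, ...) {
  simulation_config(genome_length = genome_length, n_dsrna_loci = n_dsrna,
                    n_splice_loci = n_splice, n_noise_loci = n_noise,
                    seed = seed, ...)
}

get_corpus <- function(config, tag) {
  key <- paste0(tag, "_", config$seed)
  if (!is.null(.corpus_cache[[key]])) return(.corpus_cache[[key]])
  dir <- file.path(tempdir(), paste0("corpus_", key))
  corpus <- simulate_corpus(config, dir)
  corpus$reads <- as_read_table(corpus$alignments)
  .corpus_cache[[key]] <- corpus
  corpus
}

get_small_corpus <- function(seed = 11) {
  get_corpus(small_sim_config(seed), "small")
}

# hand-rolled SAM writer for fixtures built inline in tests
write_fixture_sam <- function(path, chrom, chrom_len, records) {
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len)
  )
  for (r in records) {
    opt <- if (!is.null(r$cs)) paste0("\tcs:Z:", r$cs) else ""
    lines <- c(lines, paste0(
      r$id, "\t", r$flag %||% 0L, "\t", chrom, "\t", r$pos + 1L, "\t60\t",
      r$cigar, "\t*\t0\t0\t", r$seq %||% "*", "\t*", opt
    ))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal read table constructed directly (no file round trip)
make_read_table <- function(chrom, specs) {
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    skips <- if (is.null(s$skips)) {
      tibble::tibble(start = numeric(0), end = numeric(0), length = numeric(0))
    } else {
      tibble::tibble(start = sapply(s$skips, `[`, 1),
                     end = sapply(s$skips, `[`, 2)) |>
        dplyr::mutate(length = end - start)
    }
    tibble::tibble(read_id = s$id %||% paste0("r", i), chrom = chrom,
                   aln_start = s$start, aln_end = s$end, skips = list(skips))
  })
  dplyr::bind_rows(rows)
}

# deterministic stand-in folding engine: pairs nothing, fixed mfe per length
flat_engine <- function(mfe_per_nt = 0) {
  function(seq) {
    list(dotbracket = strrep(".", nchar(seq)), mfe = mfe_per_nt * nchar(seq))
  }
}
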