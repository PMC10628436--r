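#' Thermodynamic folding engine backed by ViennaRNA's RNAfold
#'
#' Returns a closure mapping a nucleotide sequence to its minimum-free-energy
#' secondary structure. The closure calls the `RNAfold` executable with
#' default energy parameters; the narrow sequence-in / dot-bracket-out
#' interface lets tests substitute a deterministic stand-in engine.
#'
#' @return A function `f(seq)` returning `list(dotbracket =, mfe =)` with
#'   `mfe` in kcal/mol.
#' @export
rnafold_engine <- function() {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    abort(paste0("folding engine unavailable: RNAfold (ViennaRNA package) ",
                 "not found on PATH"))
  }
  function(seq) {
    out <- system2(exe, args = c("--noPS"), input = c(">q", seq),
                   stdout = TRUE, stderr = FALSE)
    line <- out[length(out)]
    m <- regmatches(line, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", line))
    if (length(m) == 0L) abort(paste0("RNAfold output not understood: ", line))
    mfe <- as.numeric(gsub("[()[:space:]]", "", m))
    db <- sub("\\s*\\(\\s*-?[0-9.]+\\)\\s*$", "", line)
    list(dotbracket = db, mfe = mfe)
  }
}

#' Fold a sequence and derive its adjusted minimum free energy
#'
#' The adjusted MFE (AMFE) normalises the minimum free energy by sequence
#' length: `amfe = mfe / length * 100`, in kcal/mol per 100 nt, so that
#' structural stability is comparable across regions of different size.
#'
#' @param seq Nucleotide string (ACGTUN, case-insensitive; T is mapped to U).
#' @param engine Folding engine, a function as returned by
#'   [rnafold_engine()] (the default).
#' @param max_len Maximum sequence length accepted (nt).
#' @return A list: `sequence_length`, `dotbracket`, `mfe` (kcal/mol),
#'   `amfe` (kcal/mol per 100 nt).
#' @export
fold_sequence <- function(seq, engine = NULL, max_len = 5000) {
  seq <- chartr("tu", "TU", toupper(seq))
  seq <- gsub("T", "U", seq, fixed = TRUE)
  n <- nchar(seq)
  if (n < 10) abort("sequence shorter than 10 nt cannot be folded")
  if (n > max_len) {
    abort(paste0("sequence of ", n, " nt exceeds folding limit ", max_len))
  }
  if (grepl("[^ACGUN]", seq)) abort("sequence contains non-ACGUN characters")
  if (is.null(engine)) engine <- rnafold_engine()
  res <- engine(seq)
  if (nchar(res$dotbracket) != n) {
    abort("folding engine returned a structure of the wrong length")
  }
  list(sequence_length = n, dotbracket = res$dotbracket, mfe = res$mfe,
       amfe = res$mfe / n * 100)
}

# pair table from dot-bracket: vector p, p[i] = partner of i or NA
pair_table <- function(db) {
  chars <- strsplit(db, "")[[1]]
  if (any(!chars %in% c("(", ")", "."))) {
    abort("dot-bracket contains characters other than '(', ')', '.'")
  }
  n <- length(chars)
  p <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) abort("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    }
  }
  if (length(stack) > 0L) abort("unbalanced dot-bracket string")
  p
}

# maximal stacked helices: runs of pairs (i,j),(i+1,j-1),...
# returns tibble oi, oj (outer pair), ii, ij (inner pair), npairs
find_helices <- function(p) {
  n <- length(p)
  opens <- which(!is.na(p) & p > seq_len(n))
  out <- list()
  used <- rep(FALSE, n)
  for (i in opens) {
    if (used[i]) next
    j <- p[i]
    oi <- i; oj <- j; np <- 0L
    while (i < j && !is.na(p[i]) && p[i] == j) {
      used[i] <- TRUE
      np <- np + 1L
      ii <- i; ij <- j
      i <- i + 1L; j <- j - 1L
    }
    out[[length(out) + 1L]] <- tibble(oi = oi, oj = oj, ii = ii, ij = ij,
                                      npairs = np)
  }
  bind_rows(out)
}

# helix h2 extends h1 when nested directly inside h1's innermost pair with
# interior loop / bulge of at most max_loop nt on each side
helix_chain_edge <- function(h1, h2, max_loop) {
  h2$oi > h1$ii && h2$oj < h1$ij &&
    (h2$oi - h1$ii - 1) <= max_loop && (h1$ij - h2$oj - 1) <= max_loop
}

#' Duplex-stem metrics of a secondary structure
#'
#' Identifies helices (maximal runs of stacked base pairs) in a dot-bracket
#' string, chains nested helices into duplexes while consecutive helices are
#' separated by interior loops or bulges of at most `max_loop` nt per side,
#' and reports the duplex with the most base pairs. The duplex span runs
#' from its outermost pair's opening to closing position; the mismatch
#' fraction is the share of span positions not paired within the duplex
#' (loops, bulges, and the terminal hairpin loop all count).
#'
#' @param dotbracket Balanced dot-bracket string.
#' @param max_loop Maximum interior loop/bulge size chained across (nt per
#'   side).
#' @return A list: `length` (base pairs in the longest duplex), `span`
#'   (nt between and including the outermost pair), `mismatch_fraction`.
#' @export
#' @examples
#' stem_report("((((....))))")
stem_report <- function(dotbracket, max_loop = 30) {
  p <- pair_table(dotbracket)
  hx <- find_helices(p)
  if (nrow(hx) == 0L) {
    return(list(length = 0L, span = 0L, mismatch_fraction = 0))
  }
  hx <- hx |> arrange(.data$oi)
  n_h <- nrow(hx)
  # best[k]: max total pairs of a chain starting at helix k
  best <- rep(NA_real_, n_h)
  chain_pairs <- function(k) {
    if (!is.na(best[k])) return(best[k])
    val <- hx$npairs[k]
    for (m in seq_len(n_h)) {
      if (m != k && helix_chain_edge(hx[k, ], hx[m, ], max_loop)) {
        val <- max(val, hx$npairs[k] + chain_pairs(m))
      }
    }
    best[k] <<- val
    val
  }
  totals <- vapply(seq_len(n_h), chain_pairs, numeric(1))
  k0 <- which.max(totals)
  len <- totals[k0]
  span <- hx$oj[k0] - hx$oi[k0] + 1
  list(length = as.integer(len), span = as.integer(span),
       mismatch_fraction = (span - 2 * len) / span)
}

#' Classify a model-positive candidate by its folded structure
#'
#' A candidate qualifies as a novel long dsRNA when its longest duplex stem
#' has at least `min_stem` base pairs with at most `max_mismatch` unpaired
#' span fraction and the adjusted MFE is at most `amfe_max`; all bounds are
#' inclusive. Anything else is a generally structured RNA.
#'
#' @param fold Result of [fold_sequence()].
#' @param stem Result of [stem_report()].
#' @param min_stem Minimum stem length (bp).
#' @param max_mismatch Maximum mismatch fraction.
#' @param amfe_max Maximum adjusted MFE (kcal/mol per 100 nt).
#' @return `"novel_long_dsRNA"` or `"structured_RNA"`.
#' @export
classify_structure <- function(fold, stem, min_stem = 200,
                               max_mismatch = 0.20, amfe_max = -35.0) {
  if (stem$length >= min_stem && stem$mismatch_fraction <= max_mismatch &&
      fold$amfe <= amfe_max) {
    "novel_long_dsRNA"
  } else {
    "structured_RNA"
  }
}
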