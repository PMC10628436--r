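# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles with different code paths than the package.

# --- reference walk over a CIGAR string, one character at a time -----------
oracle_cigar_walk <- function(cigar, pos) {
  chars <- strsplit(cigar, "")[[1]]
  num <- ""
  ref <- pos
  skips <- list()
  for (ch in chars) {
    if (ch %in% as.character(0:9)) {
      num <- paste0(num, ch)
    } else {
      len <- as.numeric(num)
      num <- ""
      if (ch == "N") skips[[length(skips) + 1L]] <- c(ref, ref + len)
      if (ch %in% c("M", "D", "N", "X", "=")) ref <- ref + len
    }
  }
  list(end = ref, skips = skips)
}

# --- per-window feature recomputation with plain loops ---------------------
# aln: tibble with pos, cigar (simulated records); genome_str: one character
# string. Window coordinates 0-based half-open.
oracle_window_features <- function(aln, genome_str, start, end,
                                   min_skip_len = 20) {
  total <- 0L
  skip_starts <- c(); skip_ends <- c(); skip_read <- c()
  for (r in seq_len(nrow(aln))) {
    w <- oracle_cigar_walk(aln$cigar[r], aln$pos[r])
    if (aln$pos[r] < end && w$end > start) total <- total + 1L
    for (sk in w$skips) {
      if (sk[2] - sk[1] >= min_skip_len && sk[1] >= start && sk[1] < end) {
        skip_starts <- c(skip_starts, sk[1])
        skip_ends <- c(skip_ends, sk[2])
        skip_read <- c(skip_read, r)
      }
    }
  }
  n_skipping <- length(unique(skip_read))
  res <- list(
    total_reads = total, skipping_reads = n_skipping,
    skip_ratio = n_skipping / total,
    len_skip = mean(skip_ends - skip_starts)
  )
  grp_s <- oracle_partition_groups(sort(skip_starts), 100)
  grp_e <- oracle_partition_groups(sort(skip_ends), 100)
  res$group_num <- (length(grp_s) + length(grp_e)) / 2
  psd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
  res$std_start <- mean(sapply(grp_s, psd))
  res$std_end <- mean(sapply(grp_e, psd))
  gc <- numeric(0)
  dstart <- character(0); dend <- character(0)
  for (k in seq_along(skip_starts)) {
    seg <- substr(genome_str, skip_starts[k] + 1, skip_ends[k])
    letters <- strsplit(seg, "")[[1]]
    gc <- c(gc, sum(letters %in% c("G", "C")) / length(letters))
    dstart <- c(dstart, substr(seg, 1, 2))
    dend <- c(dend, substr(seg, nchar(seg) - 1, nchar(seg)))
  }
  res$gc_skip <- mean(gc)
  all_d <- sort(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0)))
  for (d in all_d) {
    res[[paste0("bp_start_", d)]] <- sum(dstart == d) / sum(dstart %in% all_d)
    res[[paste0("bp_end_", d)]] <- sum(dend == d) / sum(dend %in% all_d)
  }
  res
}

# --- coarsest valid partition, independent formulation ---------------------
# validity identical to the documented rule; minimal group count found by a
# top-down recursion over the first group's end
oracle_group_valid <- function(g, radius = 100) {
  m <- if (length(g) %% 2 == 1) {
    sort(g)[(length(g) + 1) / 2]
  } else {
    mean(sort(g)[length(g) / 2 + c(0, 1)])
  }
  (max(g) - m) < radius && (m - min(g)) < radius
}

oracle_min_parts <- function(pos, radius = 100) {
  n <- length(pos)
  memo <- rep(NA_real_, n + 1)
  rec <- function(i) {
    if (i > n) return(0)
    if (!is.na(memo[i])) return(memo[i])
    best <- Inf
    for (j in i:n) {
      if (oracle_group_valid(pos[i:j], radius)) {
        best <- min(best, 1 + rec(j + 1))
      }
    }
    memo[i] <<- best
    best
  }
  rec(1)
}

# stage-1 single-linkage clusters, then minimal valid partition per cluster
oracle_partition_groups <- function(pos, radius = 100) {
  pos <- sort(pos)
  out <- list()
  cluster <- pos[1]
  flush <- function(cl) {
    k <- oracle_min_parts(cl, radius)
    # reconstruct one minimal partition greedily from the left (longest first
    # group consistent with minimality)
    parts <- list()
    i <- 1
    while (i <= length(cl)) {
      pick <- NA
      for (j in i:length(cl)) {
        if (oracle_group_valid(cl[i:j], radius) &&
            oracle_min_parts_from(cl, j + 1, radius) ==
            oracle_min_parts_from(cl, i, radius) - 1) {
          pick <- j
        }
      }
      parts[[length(parts) + 1L]] <- cl[i:pick]
      i <- pick + 1
    }
    parts
  }
  for (k in seq_along(pos)[-1]) {
    if (pos[k] - cluster[length(cluster)] > radius) {
      out <- c(out, flush(cluster))
      cluster <- pos[k]
    } else {
      cluster <- c(cluster, pos[k])
    }
  }
  c(out, flush(cluster))
}

oracle_min_parts_from <- function(pos, i, radius = 100) {
  if (i > length(pos)) return(0)
  oracle_min_parts(pos[i:length(pos)], radius)
}

# --- helix chains in a dot-bracket, exhaustive -----------------------------
oracle_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") {
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  pairs
}

oracle_stem_report <- function(db, max_loop = 30) {
  pairs <- oracle_pairs(db)
  if (length(pairs) == 0L) return(list(length = 0L, mismatch_fraction = 0))
  ptab <- integer(nchar(db))
  for (p in pairs) { ptab[p[1]] <- p[2]; ptab[p[2]] <- p[1] }
  # helices: group pairs by stacking
  op <- sort(vapply(pairs, `[`, numeric(1), 1))
  helix_of <- integer(0)
  helices <- list()
  for (i in op) {
    j <- ptab[i]
    placed <- FALSE
    for (h in seq_along(helices)) {
      last <- helices[[h]][[length(helices[[h]])]]
      if (i == last[1] + 1 && j == last[2] - 1) {
        helices[[h]][[length(helices[[h]]) + 1L]] <- c(i, j)
        placed <- TRUE
        break
      }
    }
    if (!placed) helices[[length(helices) + 1L]] <- list(c(i, j))
  }
  hinfo <- lapply(helices, function(h) {
    list(oi = h[[1]][1], oj = h[[1]][2],
         ii = h[[length(h)]][1], ij = h[[length(h)]][2], np = length(h))
  })
  edge <- function(a, b) {
    b$oi > a$ii && b$oj < a$ij &&
      (b$oi - a$ii - 1) <= max_loop && (a$ij - b$oj - 1) <= max_loop
  }
  best_len <- 0L; best_span <- 0L
  dfs <- function(k, total) {
    extended <- FALSE
    for (m in seq_along(hinfo)) {
      if (m != k && edge(hinfo[[k]], hinfo[[m]])) {
        extended <- TRUE
        dfs(m, total + hinfo[[m]]$np)
      }
    }
    if (total > best_len) {
      best_len <<- total
    }
    invisible(NULL)
  }
  # try every helix as chain head, tracking span of the head
  best <- list(length = 0L, span = 0L)
  for (k in seq_along(hinfo)) {
    best_len <- 0L
    dfs(k, hinfo[[k]]$np)
    if (best_len > best$length) {
      best <- list(length = best_len,
                   span = hinfo[[k]]$oj - hinfo[[k]]$oi + 1)
    }
  }
  list(length = best$length,
       mismatch_fraction = (best$span - 2 * best$length) / best$span)
}

# --- random balanced dot-bracket strings -----------------------------------
random_dotbracket <- function(n, p_open = 0.3, p_dot = 0.4) {
  chars <- character(n)
  depth <- 0
  for (i in seq_len(n)) {
    remaining <- n - i + 1
    if (depth >= remaining) {
      chars[i] <- ")"
      depth <- depth - 1
    } else {
      u <- runif(1)
      if (u < p_open && depth < remaining - 1) {
        chars[i] <- "("
        depth <- depth + 1
      } else if (u < p_open + p_dot || depth == 0) {
        chars[i] <- "."
      } else {
        chars[i] <- ")"
        depth <- depth - 1
      }
    }
  }
  paste(chars, collapse = "")
}
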