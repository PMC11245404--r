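# Independent brute-force oracles used to validate the optimised
# implementations. These deliberately share no code with the package
# internals: plain loops over explicit strings.

random_circle <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Literal raw ORF enumeration on the explicit `copies`-fold string: walk
# codon by codon from every start-codon position in the first copy. No
# junction or inclusion filtering.
oracle_raw_orfs <- function(S, start_codons = default_start_codons(),
                            copies = 4L) {
  L <- nchar(S)
  stops <- c("TAA", "TAG", "TGA")
  P <- paste(rep(S, copies), collapse = "")
  N <- nchar(P)
  found <- list()
  for (p in seq_len(L)) {
    if (!substr(P, p, p + 2) %in% start_codons) next
    q <- p
    stopless <- TRUE
    while (q + 2 <= N) {
      if (substr(P, q, q + 2) %in% stops) {
        stopless <- FALSE
        break
      }
      q <- q + 3
    }
    len <- if (stopless) 3 * ((N - p + 1) %/% 3) else q + 2 - p + 1
    found[[length(found) + 1]] <-
      data.frame(start = p - 1, length_nt = len, stopless = stopless,
                 end0 = (p - 1) + len - 1, frame = (p - 1) %% 3)
  }
  if (length(found) == 0) {
    data.frame(start = integer(), length_nt = integer(), stopless = logical(),
               end0 = integer(), frame = integer())
  } else {
    do.call(rbind, found)
  }
}

# Full oracle: raw enumeration, junction (wrap) retention, then literal
# longest-on-inclusion filtering.
oracle_find_orfs <- function(S, start_codons = default_start_codons(),
                             copies = 4L) {
  L <- nchar(S)
  stops <- c("TAA", "TAG", "TGA")
  P <- paste(rep(S, copies), collapse = "")
  N <- nchar(P)
  found <- list()
  for (p in seq_len(L)) {
    if (!substr(P, p, p + 2) %in% start_codons) next
    q <- p
    stopless <- TRUE
    while (q + 2 <= N) {
      if (substr(P, q, q + 2) %in% stops) {
        stopless <- FALSE
        break
      }
      q <- q + 3
    }
    len <- if (stopless) 3 * ((N - p + 1) %/% 3) else q + 2 - p + 1
    end0 <- (p - 1) + len - 1
    wraps <- end0 %/% L
    if (wraps < 1) next
    found[[length(found) + 1]] <-
      data.frame(start = p - 1, length_nt = len, stopless = stopless,
                 end0 = end0, frame = (p - 1) %% 3)
  }
  if (length(found) == 0) {
    return(data.frame(start = integer(), length_nt = integer(),
                      stopless = logical()))
  }
  df <- do.call(rbind, found)
  # literal sequence-inclusion on the circle: ORF i is dropped when a
  # longer terminating ORF j ends at the same circular stop (ends
  # congruent mod L) and contains i's sequence as a suffix
  orf_nt <- substring(P, df$start + 1, df$start + df$length_nt)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || df$stopless[i] || df$stopless[j]) next
      if ((df$end0[i] - df$end0[j]) %% L == 0 &&
          df$length_nt[j] > df$length_nt[i] &&
          endsWith(orf_nt[j], orf_nt[i])) {
        keep[i] <- FALSE
      }
    }
  }
  out <- df[keep, c("start", "length_nt", "stopless")]
  out[order(out$start, out$length_nt), , drop = FALSE]
}

orf_call_key <- function(df) {
  df <- df[order(df$start, df$length_nt), , drop = FALSE]
  paste(df$start, df$length_nt, as.integer(df$stopless), sep = ":",
        collapse = ";")
}

# All-offsets Hamming scan of one read against one window; returns
# crossing hits as offset/overhang/mismatch rows.
oracle_match_one <- function(read, window, jo, max_mm = 0) {
  m <- nchar(read)
  wl <- nchar(window)
  rs <- strsplit(read, "")[[1]]
  ws <- strsplit(window, "")[[1]]
  out <- list()
  if (m > wl) return(data.frame())
  for (o in seq_len(wl - m + 1)) {
    span <- o:(o + m - 1)
    if (!(o <= jo && (o + m - 1) >= jo + 1)) next  # must cross boundary
    mm <- sum(rs != ws[span] | rs == "N" | ws[span] == "N")
    if (mm <= max_mm) {
      out[[length(out) + 1]] <- data.frame(
        window_offset = o - 1, overhang5 = jo - o + 1,
        overhang3 = o + m - 1 - jo, mismatches = mm
      )
    }
  }
  if (length(out) == 0) data.frame() else do.call(rbind, out)
}
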