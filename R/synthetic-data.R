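# Seeded synthetic multiomic data with ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# multi-exon genes on a random genome, circles 100-3000 nt, a configurable
# fraction carrying a planted junction-spanning ORF (start codon placed
# shortly before the back-splice junction, stop after the wrap, interior
# codons free of tryptic cleavage sites so a junction-covering tryptic
# peptide is guaranteed), footprints 25-35 nt concentrated on junctions of
# coding circles with 3-nt periodicity, junction-level RNA support, and
# peptide identifications mixing true junction peptides, canonical
# peptides, decoy-derived matches and random noise. Noncoding circles are
# actively scrubbed of qualifying junction ORFs by rejection sampling so
# stage-level specificity is measurable.

#' Simulation configuration
#'
#' @param seed Master seed; every stream of randomness derives from it
#'   and identical seeds give identical outputs.
#' @param n_circ Number of circRNAs (one host gene each).
#' @param frac_coding Fraction of circles with a planted junction ORF.
#' @param circ_len_range Mature circle length range, nt.
#' @param read_len_probs Named numeric vector: footprint length
#'   distribution (support 25-35 nt, peaked at 28-30 by default).
#' @param frame0_prob Probability that a junction footprint's 5' end is
#'   in frame 0 relative to the planted ORF start.
#' @param ribo_depth_coding Junction footprints per coding circle.
#' @param ribo_depth_noncoding Range (min, max) of junction footprints
#'   per noncoding circle.
#' @param background_reads_per_circ Non-junction footprints per circle.
#' @param rna_depth_range Range of back-spliced RNA-seq reads per circle.
#' @param pep_true_per_circ Range of true junction peptides emitted per
#'   coding circle.
#' @param pep_noise_n,pep_decoy_n,pep_canonical_n Counts of random-noise,
#'   decoy-derived and canonical peptide identifications.
#' @param score_true,score_noise Normal score distributions
#'   (`c(mean, sd)`) for true/canonical vs noise/decoy identifications.
#' @param error_rate Per-base substitution error rate in reads.
#' @param n_canonical,canonical_len_range Canonical proteome size and
#'   protein length range.
#' @param planted_pep_len_range Planted CEP peptide length range, aa.
#' @param scrub_max_attempts Rejection-sampling budget when scrubbing
#'   noncoding circles of junction ORFs.
#' @param min_peptide_len CEP database peptide length floor (matches the
#'   analysis default of 11 aa).
#' @return A list of class `circpep_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_circ = 100L,
                       frac_coding = 0.3,
                       circ_len_range = c(100L, 3000L),
                       read_len_probs = c(
                         "25" = 0.04, "26" = 0.06, "27" = 0.10, "28" = 0.18,
                         "29" = 0.20, "30" = 0.18, "31" = 0.10, "32" = 0.06,
                         "33" = 0.04, "34" = 0.02, "35" = 0.02),
                       frame0_prob = 0.7,
                       ribo_depth_coding = 20L,
                       ribo_depth_noncoding = c(0L, 1L),
                       background_reads_per_circ = 3L,
                       rna_depth_range = c(5L, 50L),
                       pep_true_per_circ = c(1L, 3L),
                       pep_noise_n = 200L,
                       pep_decoy_n = 40L,
                       pep_canonical_n = 100L,
                       score_true = c(mean = 30, sd = 3),
                       score_noise = c(mean = 12, sd = 3),
                       error_rate = 0.001,
                       n_canonical = 40L,
                       canonical_len_range = c(200L, 600L),
                       planted_pep_len_range = c(15L, 35L),
                       scrub_max_attempts = 50L,
                       min_peptide_len = 11L) {
  stopifnot(frac_coding >= 0, frac_coding <= 1,
            frame0_prob >= 0, frame0_prob <= 1,
            error_rate >= 0, error_rate < 1,
            circ_len_range[1] < circ_len_range[2],
            abs(sum(read_len_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "circpep_sim_config")
}

#' Simulate a random genome with multi-exon gene models
#'
#' One host gene per circle, spread over four chromosomes, with random
#' exon (60-450 nt) and intron (50-400 nt) lengths and random strands.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector) and `genes`
#'   (tibble: `gene_id`, `chrom`, `strand`, `exon_starts`, `exon_ends`).
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, {
    n_genes <- config$n_circ
    n_chrom <- 4L
    chrom_of <- paste0("chr", ((seq_len(n_genes) - 1L) %% n_chrom) + 1L)
    pieces <- stats::setNames(vector("list", n_chrom), paste0("chr", 1:n_chrom))
    cursor <- stats::setNames(rep(0L, n_chrom), paste0("chr", 1:n_chrom))
    genes <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      chrom <- chrom_of[i]
      gap <- sample(200:800, 1)
      n_exons <- sample(3:8, 1)
      exon_lens <- sample(60:450, n_exons, replace = TRUE)
      intron_lens <- if (n_exons > 1) sample(50:400, n_exons - 1,
                                             replace = TRUE) else integer()
      pos <- cursor[chrom] + gap
      starts <- integer(n_exons)
      ends <- integer(n_exons)
      for (e in seq_len(n_exons)) {
        starts[e] <- pos
        ends[e] <- pos + exon_lens[e]
        pos <- ends[e] + if (e < n_exons) intron_lens[e] else 0L
      }
      cursor[chrom] <- pos
      gene_len <- pos - (starts[1] - gap)
      pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <- random_nt(gene_len)
      genes[[i]] <- tibble::tibble(
        gene_id = sprintf("gene%03d", i), chrom = chrom,
        strand = sample(c("+", "-"), 1),
        exon_starts = list(starts), exon_ends = list(ends)
      )
    }
    genome <- vapply(pieces, paste, character(1), collapse = "")
    list(genome = genome, genes = dplyr::bind_rows(genes))
  })
}

safe_codons <- function() {
  # interior codons of planted ORFs: no stops, no K/R (keeps the planted
  # region a single tryptic fragment spanning the junction)
  bases <- c("A", "C", "G", "T")
  all_cod <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all_cod, c(STOP_CODONS, "AAA", "AAG",
                     "CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
}

# Write mature sequence M back into the genome across the exon run.
patch_genome <- function(genome, chrom, strand, starts, ends, M) {
  genomic <- if (strand == "-") revcomp(M) else M
  offset <- 0L
  s <- genome[[chrom]]
  for (e in seq_along(starts)) {
    len <- ends[e] - starts[e]
    piece <- substr(genomic, offset + 1L, offset + len)
    substr(s, starts[e] + 1L, ends[e]) <- piece
    offset <- offset + len
  }
  genome[[chrom]] <- s
  genome
}

#' Simulate circRNAs with planted junction ORFs and ground truth
#'
#' Each circle takes a contiguous exon run of its host gene. Coding
#' circles get a designed junction-spanning ORF (ATG placed 4+ nt before
#' the junction, stop after the wrap, cleavage-free interior); noncoding
#' circles are rejection-sampled until they carry no CEP-database-
#' qualifying junction ORF (up to `scrub_max_attempts`, else flagged
#' `coding_ambiguous`). The designed sequences are written back into the
#' genome so that BED12 + genome -> [build_mature_sequence()] reproduces
#' them exactly.
#'
#' @param config A [sim_config()].
#' @param sim_genome Output of [simulate_genome()].
#' @return List: `circs` (circRNA tibble with `mature_seq`), `genome`
#'   (patched), `truth` (per-circle tibble: `circ_id`, `has_planted_orf`,
#'   `coding_ambiguous`, `planted_start`, `planted_len_nt`,
#'   `planted_peptide`).
#' @export
simulate_circrnas <- function(config, sim_genome) {
  genome <- sim_genome$genome
  genes <- sim_genome$genes
  n <- config$n_circ
  safe <- safe_codons()
  withr::with_seed(config$seed + 1L, {
    coding <- sample(rep(c(TRUE, FALSE),
                         c(round(config$frac_coding * n),
                           n - round(config$frac_coding * n))))
    circ_rows <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- genes[i, ]
      starts_all <- g$exon_starts[[1]]
      ends_all <- g$exon_ends[[1]]
      lens <- ends_all - starts_all
      # contiguous exon run with total length inside circ_len_range
      runs <- list()
      for (a in seq_along(lens)) for (b in a:length(lens)) {
        tot <- sum(lens[a:b])
        if (tot >= config$circ_len_range[1] && tot <= config$circ_len_range[2])
          runs[[length(runs) + 1L]] <- c(a, b)
      }
      if (length(runs) == 0) {
        abort_circpep("Gene has no exon run inside `circ_len_range`.",
                      "circpep_input_error")
      }
      run <- runs[[sample.int(length(runs), 1)]]
      idx <- run[1]:run[2]
      starts <- starts_all[idx]
      ends <- ends_all[idx]
      L <- sum(ends - starts)

      design <- design_mature(L, coding[i], config, safe)
      genome <- patch_genome(genome, g$chrom, g$strand, starts, ends,
                             design$M)
      circ_rows[[i]] <- tibble::tibble(
        circ_id = sprintf("circ%03d", i), chrom = g$chrom,
        strand = g$strand, exon_starts = list(starts),
        exon_ends = list(ends), mature_seq = design$M,
        host_gene = g$gene_id
      )
      truth_rows[[i]] <- tibble::tibble(
        circ_id = sprintf("circ%03d", i),
        circ_len = L,
        has_planted_orf = coding[i],
        coding_ambiguous = design$ambiguous,
        planted_start = design$planted_start,
        planted_len_nt = design$planted_len,
        planted_peptide = design$planted_peptide
      )
    }
    circs <- validate_circs(dplyr::bind_rows(circ_rows), need_seq = TRUE)
    list(circs = circs, genome = genome,
         truth = dplyr::bind_rows(truth_rows))
  })
}

# Design one mature circle sequence (runs inside the caller's RNG stream).
design_mature <- function(L, coding, config, safe) {
  min_len <- config$min_peptide_len
  probe <- function(M) {
    orfs <- find_circ_orfs(circ_tbl("probe", mature_seq = M))
    build_cep_db(orfs, min_peptide_len = min_len)
  }
  if (coding) {
    for (attempt in seq_len(config$scrub_max_attempts)) {
      max_npep <- min(config$planted_pep_len_range[2], (L - 6L) %/% 3L - 1L)
      npep <- sample(config$planted_pep_len_range[1]:max_npep, 1)
      O <- 3L * (npep + 1L)
      d1 <- sample(4:(O - 6L), 1)  # nt of the ORF upstream of the junction
      p0 <- L - d1                  # 0-based circular start
      codons <- c("ATG", sample(safe, npep - 1L, replace = TRUE),
                  sample(STOP_CODONS, 1))
      orf_nt <- paste(codons, collapse = "")
      M <- random_nt(L)
      doubled <- paste0(M, M)
      substr(doubled, p0 + 1L, p0 + O) <- orf_nt
      M <- paste0(substr(doubled, L + 1L, p0 + O),
                  substr(doubled, nchar(orf_nt) + p0 - L + 1L, L))
      # verify the planted entry yields a junction-covering tryptic peptide
      db <- probe(M)
      ok <- FALSE
      if (nrow(db) > 0) {
        frag_ok <- purrr::map_lgl(seq_len(nrow(db)), function(j) {
          frags <- digest_trypsin_pos(db$peptide[j])
          any(purrr::map_lgl(db$junction_spans[[j]], function(sp) {
            any(frags$start <= sp[1] & frags$end >= sp[2] &
                  (frags$end - frags$start + 1L) >= 7L)
          }))
        })
        ok <- any(frag_ok)
      }
      if (ok) {
        return(list(M = M, ambiguous = FALSE, planted_start = p0,
                    planted_len = O,
                    planted_peptide = translate_orf(orf_nt)))
      }
    }
    abort_circpep("Failed to design a recoverable planted ORF.",
                  "circpep_input_error")
  } else {
    for (attempt in seq_len(config$scrub_max_attempts)) {
      M <- random_nt(L)
      if (nrow(probe(M)) == 0) {
        return(list(M = M, ambiguous = FALSE, planted_start = NA_integer_,
                    planted_len = NA_integer_,
                    planted_peptide = NA_character_))
      }
    }
    list(M = M, ambiguous = TRUE, planted_start = NA_integer_,
         planted_len = NA_integer_, planted_peptide = NA_character_)
  }
}

apply_read_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(list(seq = seq, n_errors = 0L))
  chars <- strsplit(seq, "")[[1]]
  flip <- which(stats::runif(length(chars)) < error_rate)
  for (j in flip) {
    chars[j] <- sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1)
  }
  list(seq = paste(chars, collapse = ""), n_errors = length(flip))
}

#' Simulate ribosome footprints
#'
#' Junction-crossing footprints for coding circles at
#' `ribo_depth_coding`, 0 to `ribo_depth_noncoding[2]` for noncoding
#' circles, plus non-junction background reads for every circle. Read
#' lengths follow `read_len_probs` (all inside 25-35 nt); 5' ends of
#' coding-circle junction reads are frame-biased with `frame0_prob`
#' relative to the planted ORF start; bases are substituted at
#' `error_rate`.
#'
#' @param config A [sim_config()].
#' @param circs,truth From [simulate_circrnas()].
#' @return Tibble: `read_id`, `seq`, `circ_id_origin`, `kind`
#'   ("junction"/"background"), `n_errors`, `frame_offset` (5'-end offset
#'   mod 3 relative to the planted ORF start; NA when no ORF),
#'   `overhang5_true`, `overhang3_true`.
#' @export
simulate_ribo_reads <- function(config, circs, truth) {
  lens <- as.integer(names(config$read_len_probs))
  withr::with_seed(config$seed + 2L, {
    rows <- vector("list", nrow(circs))
    for (i in seq_len(nrow(circs))) {
      M <- circs$mature_seq[i]
      L <- nchar(M)
      doubled <- paste0(M, M)
      tr <- truth[truth$circ_id == circs$circ_id[i], ]
      depth <- if (tr$has_planted_orf) {
        config$ribo_depth_coding
      } else {
        sample(config$ribo_depth_noncoding[1]:config$ribo_depth_noncoding[2], 1)
      }
      out <- list()
      for (j in seq_len(depth)) {
        m <- sample(lens, 1, prob = config$read_len_probs)
        s_cand <- (L - m + 1L):(L - 1L)  # 0-based 5' start: crosses junction
        w <- if (!is.na(tr$planted_start)) {
          ifelse((s_cand - tr$planted_start) %% 3L == 0L,
                 config$frame0_prob, (1 - config$frame0_prob) / 2)
        } else {
          rep(1, length(s_cand))
        }
        s <- sample(s_cand, 1, prob = w)
        read <- apply_read_errors(substr(doubled, s + 1L, s + m),
                                  config$error_rate)
        out[[length(out) + 1L]] <- tibble::tibble(
          seq = read$seq, circ_id_origin = circs$circ_id[i],
          kind = "junction", n_errors = read$n_errors,
          frame_offset = if (!is.na(tr$planted_start)) {
            as.integer((s - tr$planted_start) %% 3L)
          } else NA_integer_,
          overhang5_true = L - s, overhang3_true = m - (L - s)
        )
      }
      for (j in seq_len(config$background_reads_per_circ)) {
        m <- sample(lens, 1, prob = config$read_len_probs)
        s <- sample(0:(L - m), 1)
        read <- apply_read_errors(substr(doubled, s + 1L, s + m),
                                  config$error_rate)
        out[[length(out) + 1L]] <- tibble::tibble(
          seq = read$seq, circ_id_origin = circs$circ_id[i],
          kind = "background", n_errors = read$n_errors,
          frame_offset = NA_integer_, overhang5_true = NA_integer_,
          overhang3_true = NA_integer_
        )
      }
      rows[[i]] <- dplyr::bind_rows(out)
    }
    reads <- dplyr::bind_rows(rows)
    reads$read_id <- sprintf("read%05d", seq_len(nrow(reads)))
    dplyr::relocate(reads, "read_id")
  })
}

#' Simulate 5'-end offsets of footprints on linear CDS controls
#'
#' Emulates the input of [frame_periodicity()]: offsets relative to
#' annotated ORF starts, in frame 0 with probability `frame0_prob` and
#' in frames 1/2 with equal shares of the remainder.
#'
#' @param n Number of offsets.
#' @param frame0_prob Frame-0 probability (default 0.7).
#' @param seed Seed.
#' @return Integer vector of offsets.
#' @export
simulate_frame_offsets <- function(n, frame0_prob = 0.7, seed = 1L) {
  withr::with_seed(seed, {
    f <- sample(0:2, n, replace = TRUE,
                prob = c(frame0_prob, (1 - frame0_prob) / 2,
                         (1 - frame0_prob) / 2))
    3L * sample(0:100, n, replace = TRUE) + f
  })
}

#' Simulate a canonical proteome
#'
#' @param config A [sim_config()].
#' @return Tibble with `seq_id`, `seq`.
#' @export
simulate_canonical_proteome <- function(config) {
  withr::with_seed(config$seed + 4L, {
    tibble::tibble(
      seq_id = sprintf("LEP%03d", seq_len(config$n_canonical)),
      seq = vapply(seq_len(config$n_canonical), function(i) {
        n <- sample(config$canonical_len_range[1]:config$canonical_len_range[2], 1)
        paste(sample(.AA20, n, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

#' Simulate peptide identifications
#'
#' True junction-spanning tryptic peptides from planted circles (scores
#' from the "true" normal distribution), canonical tryptic peptides
#' (true distribution), decoy-derived tryptic fragments and random noise
#' peptides (both from the "noise" distribution that governs decoy
#' matches).
#'
#' @param config A [sim_config()].
#' @param cep_db CEP database built from the simulated circles.
#' @param decoys Decoy pool for the same database.
#' @param canonical Canonical proteome tibble.
#' @param truth Truth tibble from [simulate_circrnas()].
#' @return Tibble: `pep_seq`, `score`, `sample`, `origin`
#'   ("true"/"canonical"/"decoy"/"noise"), `circ_id_origin`.
#' @export
simulate_peptides <- function(config, cep_db, decoys, canonical, truth) {
  withr::with_seed(config$seed + 3L, {
    rows <- list()
    planted <- truth$circ_id[truth$has_planted_orf & !truth$coding_ambiguous]
    for (cid in planted) {
      entries <- cep_db[!is.na(cep_db$circ_id) & cep_db$circ_id == cid, ]
      frags <- character()
      for (j in seq_len(nrow(entries))) {
        fp <- digest_trypsin_pos(entries$peptide[j])
        covers <- purrr::map_lgl(seq_len(nrow(fp)), function(k) {
          any(purrr::map_lgl(entries$junction_spans[[j]], function(sp) {
            fp$start[k] <= sp[1] && fp$end[k] >= sp[2]
          }))
        })
        frags <- c(frags, fp$peptide[covers & nchar(fp$peptide) >= 7L])
      }
      frags <- unique(frags)
      if (length(frags) == 0) next
      n_true <- sample(config$pep_true_per_circ[1]:config$pep_true_per_circ[2], 1)
      picked <- sample(frags, min(n_true, length(frags)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pep_seq = picked,
        score = stats::rnorm(length(picked), config$score_true["mean"],
                             config$score_true["sd"]),
        origin = "true", circ_id_origin = cid
      )
    }
    canon_frags <- unlist(lapply(canonical$seq, digest_trypsin))
    canon_frags <- unique(canon_frags[nchar(canon_frags) >= 7 &
                                        nchar(canon_frags) <= 35])
    picked <- sample(canon_frags, min(config$pep_canonical_n,
                                      length(canon_frags)))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pep_seq = picked,
      score = stats::rnorm(length(picked), config$score_true["mean"],
                           config$score_true["sd"]),
      origin = "canonical", circ_id_origin = NA_character_
    )
    decoy_frags <- unlist(lapply(decoys$peptide, digest_trypsin))
    decoy_frags <- unique(decoy_frags[nchar(decoy_frags) >= 6])
    if (length(decoy_frags) > 0) {
      picked <- sample(decoy_frags, min(config$pep_decoy_n,
                                        length(decoy_frags)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pep_seq = picked,
        score = stats::rnorm(length(picked), config$score_noise["mean"],
                             config$score_noise["sd"]),
        origin = "decoy", circ_id_origin = NA_character_
      )
    }
    noise <- vapply(seq_len(config$pep_noise_n), function(i) {
      paste(sample(.AA20, sample(7:20, 1), replace = TRUE), collapse = "")
    }, character(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      pep_seq = noise,
      score = stats::rnorm(length(noise), config$score_noise["mean"],
                           config$score_noise["sd"]),
      origin = "noise", circ_id_origin = NA_character_
    )
    out <- dplyr::bind_rows(rows)
    out$sample <- "S1"
    out[sample.int(nrow(out)), ]
  })
}

#' Simulate junction-level RNA-seq support
#'
#' @param config A [sim_config()].
#' @param circs Simulated circRNA tibble.
#' @return Tibble: `circ_id`, `n_bsj_reads`.
#' @export
simulate_rna_counts <- function(config, circs) {
  withr::with_seed(config$seed + 5L, {
    tibble::tibble(
      circ_id = circs$circ_id,
      n_bsj_reads = sample(config$rna_depth_range[1]:config$rna_depth_range[2],
                           nrow(circs), replace = TRUE)
    )
  })
}

#' Generate the full synthetic dataset with ground truth
#'
#' Runs every generator and assembles the per-circle ground-truth
#' manifest, including the expected outcome of each pipeline stage under
#' the default analysis thresholds (computed from the emitted reads and
#' peptides, so truth and data are consistent by construction).
#'
#' @param config A [sim_config()].
#' @return List: `config`, `genome`, `genes`, `circs`, `truth`, `reads`,
#'   `rna_counts`, `peptides`, `canonical`, `cep_db`, `decoys`.
#' @export
simulate_circ_dataset <- function(config = sim_config()) {
  sg <- simulate_genome(config)
  sc <- simulate_circrnas(config, sg)
  canonical <- simulate_canonical_proteome(config)
  orfs <- find_circ_orfs(sc$circs)
  cep_db <- build_cep_db(orfs, min_peptide_len = config$min_peptide_len)
  canon_peps <- unique(unlist(lapply(canonical$seq, digest_trypsin)))
  reads <- simulate_ribo_reads(config, sc$circs, sc$truth)
  rna_counts <- simulate_rna_counts(config, sc$circs)

  # expected stage outcomes under default thresholds (mismatch-free
  # matching): unique error-free junction reads with >= 4 nt overhang
  expected_ribo <- reads |>
    dplyr::filter(.data$kind == "junction", .data$n_errors == 0L) |>
    dplyr::distinct(.data$circ_id_origin, .data$seq, .keep_all = TRUE) |>
    dplyr::group_by(circ_id = .data$circ_id_origin) |>
    dplyr::summarise(n_eligible = sum(pmin(.data$overhang5_true,
                                           .data$overhang3_true) >= 4L),
                     .groups = "drop")
  truth <- sc$truth |>
    dplyr::left_join(expected_ribo, by = "circ_id") |>
    tidyr::replace_na(list(n_eligible = 0L)) |>
    dplyr::left_join(rna_counts, by = "circ_id") |>
    dplyr::mutate(
      is_candidate = .data$n_bsj_reads >= 2L,
      expected_ribosome_associated = .data$n_eligible >= 2L
    )

  # the peptide search downstream is restricted to ribosome-associated
  # circles; build the decoy pool over that same search database so the
  # planted decoy-derived identifications match it
  assoc_ids <- truth$circ_id[truth$expected_ribosome_associated]
  search_db <- cep_db[cep_db$circ_id %in% assoc_ids, , drop = FALSE]
  decoys <- if (nrow(search_db) > 0) {
    build_decoy_pool(search_db, seed = config$seed + 1000003L,
                     canonical_peptides = canon_peps)
  } else {
    cep_db[0, ]
  }
  peptides <- simulate_peptides(config, cep_db, decoys, canonical, truth)

  truth <- truth |>
    dplyr::left_join(
      dplyr::count(dplyr::filter(peptides, .data$origin == "true"),
                   circ_id = .data$circ_id_origin, name = "n_true_peptides"),
      by = "circ_id"
    ) |>
    tidyr::replace_na(list(n_true_peptides = 0L)) |>
    dplyr::mutate(
      expected_ms_supported = .data$expected_ribosome_associated &
        .data$n_true_peptides > 0L
    )
  list(config = config, genome = sc$genome, genes = sg$genes,
       circs = sc$circs, truth = truth, reads = reads,
       rna_counts = rna_counts, peptides = peptides, canonical = canonical,
       cep_db = cep_db, decoys = decoys)
}
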