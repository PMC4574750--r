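#' Footprint geometry presets
#'
#' A preset fixes, per (length class, ribosome state), the number of
#' nucleotides protected 5' of the P-site codon (`L5`) and 3' of the
#' A-site codon (`L3`), with `L5 + 6 + L3 = length` (two-codon P/A
#' core), plus the mixture weights of the length classes within each
#' state, the phase fidelity, and the pause factors.
#'
#' `"cr27"` encodes a Chlamydomonas-like geometry: 27-nt elongation
#' footprints protecting 11 nt 5' of the P-site codon and 10 nt 3' of
#' the A-site codon, 28-nt elongation footprints extended 1 nt at the
#' 5' end, 28-nt termination footprints extended 1 nt at the 3' end and
#' 29-nt termination footprints extended 1 nt at each end. `"mm29"`
#' encodes a mouse-like geometry: 28-30-nt elongation footprints with
#' 12 nt protected 5' of the P-site codon (29-nt class: `L5 = 12`,
#' `L3 = 11`) and 30-nt termination footprints extended 1 nt at the 3'
#' end relative to the 29-nt class.
#'
#' @param name `"cr27"`, `"mm29"` (aliases `"cr-27"`, `"mm-29"`) or
#'   `"custom"` (then `classes` must be given).
#' @param fidelity Phase fidelity `f` in (1/3, 1]: each footprint's 5'
#'   end is jittered by +/-1 nt with probability `(1 - f)/2` per side.
#' @param init_pause Relative footprint density at the start codon
#'   (initiating ribosome, P-site on the start codon) compared with one
#'   interior codon; produces the start-proximal metagene peak.
#' @param term_pause Relative footprint density at the stop codon
#'   (terminating ribosome, stop codon in the A-site).
#' @param classes For `"custom"`: tibble `length`, `state`, `L5`, `L3`,
#'   `weight` (weights normalised within state).
#' @return List of class `geometry_preset`.
#' @export
geometry_preset <- function(name = c("cr27", "mm29", "custom", "cr-27", "mm-29"),
                            fidelity = 0.95, init_pause = 3, term_pause = 3,
                            classes = NULL) {
  name <- match.arg(name)
  name <- sub("-", "", name, fixed = TRUE)
  if (name == "cr27") {
    classes <- tibble(
      length = c(27L, 28L, 28L, 29L),
      state = c("elongation", "elongation", "termination", "termination"),
      L5 = c(11L, 12L, 11L, 12L),
      L3 = c(10L, 10L, 11L, 11L),
      weight = c(0.75, 0.25, 0.6, 0.4)
    )
  } else if (name == "mm29") {
    classes <- tibble(
      length = c(28L, 29L, 30L, 30L),
      state = c("elongation", "elongation", "elongation", "termination"),
      L5 = c(12L, 12L, 12L, 12L),
      L3 = c(10L, 11L, 12L, 12L),
      weight = c(0.2, 0.6, 0.2, 1.0)
    )
  } else if (is.null(classes)) {
    abort("custom preset requires a classes table")
  }
  if (any(classes$L5 + 6L + classes$L3 != classes$length)) {
    abort("invalid geometry: L5 + 6 + L3 must equal the footprint length")
  }
  if (any(classes$L5 < 0) || any(classes$L3 < 0)) {
    abort("L5 and L3 must be non-negative")
  }
  stopifnot(fidelity > 1 / 3, fidelity <= 1, init_pause > 0, term_pause > 0)
  classes <- classes %>%
    group_by(.data$state) %>%
    mutate(weight = .data$weight / sum(.data$weight)) %>%
    ungroup()
  structure(list(name = name, classes = classes, fidelity = fidelity,
                 init_pause = init_pause, term_pause = term_pause),
            class = "geometry_preset")
}

# Codon alphabet helpers for sequence construction.
.codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  list(all = all, stops = c("TAA", "TAG", "TGA"),
       sense = setdiff(all, c("TAA", "TAG", "TGA")))
})

# sample one integer from lo..hi (safe for lo == hi, unlike sample())
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

random_nt <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# An ORF of k sense codons: ATG + (k - 1) random sense codons + stop.
random_orf <- function(k, gc) {
  w <- gc_content(.codons$sense) * gc + (1 - gc_content(.codons$sense)) *
    (1 - gc)
  body <- if (k > 1) {
    paste(sample(.codons$sense, k - 1L, replace = TRUE, prob = w),
          collapse = "")
  } else ""
  paste0("ATG", body, sample(.codons$stops, 1L))
}

#' Generate a synthetic transcriptome with known ORF structure
#'
#' Builds mRNA-like transcripts (5' leader + main ORF + 3' trailer)
#' with optional planted uORFs and internal overlapping ORFs, plus
#' rRNA-like contaminant transcripts. Planted ORFs begin with AUG, end
#' with the nearest in-frame canonical stop and contain no premature
#' in-frame stop, so the de novo scanner recovers them exactly. The
#' whole construction is reproducible under `seed`.
#'
#' @param n_transcripts Number of mRNA transcripts.
#' @param orf_codons Range of main-ORF sense-codon counts.
#' @param utr5,utr3 Ranges of leader/trailer lengths (nt); minimum 20
#'   so that footprints around starts and stops stay in bounds.
#' @param gc GC target of the generated sequence.
#' @param uorf_prob Probability a transcript carries one planted uORF.
#' @param uorf_codons Range of uORF sense-codon counts (clipped to the
#'   leader).
#' @param overlap_prob Probability of one planted internal overlapping
#'   ORF (different frame, inside the main CDS).
#' @param n_rrna Number of rRNA-like contaminant transcripts.
#' @param rrna_length Length of each rRNA transcript.
#' @param seed Integer seed (mandatory).
#' @return List of class `ribo_sim_truth`: `transcripts` (transcript
#'   tibble with the main CDS annotated and categories set), `orfs`
#'   (tibble `orf_id`, `transcript_id`, `type`, `start`, `end`,
#'   `frame`, `level` — the translated ORFs with their relative
#'   translation levels), `rna_levels` (per-transcript RNA abundance),
#'   `seed`, `config`.
#' @export
make_transcriptome <- function(n_transcripts = 50L, orf_codons = c(60L, 150L),
                               utr5 = c(30L, 80L), utr3 = c(30L, 60L),
                               gc = 0.5, uorf_prob = 0.3,
                               uorf_codons = c(3L, 16L), overlap_prob = 0.1,
                               n_rrna = 2L, rrna_length = 800L, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (utr5[1] < 20L || utr3[1] < 20L) {
    abort("leaders and trailers must be at least 20 nt")
  }
  if (orf_codons[1] < 2L) abort("main ORFs need at least 2 sense codons")
  withr::with_seed(seed, {
    tx_list <- vector("list", n_transcripts)
    orf_list <- list()
    for (i in seq_len(n_transcripts)) {
      id <- sprintf("tx%04d", i)
      k <- sample_range(orf_codons[1], orf_codons[2])
      u5 <- sample_range(utr5[1], utr5[2])
      u3 <- sample_range(utr3[1], utr3[2])
      leader <- random_nt(u5, gc)
      orf <- random_orf(k, gc)
      trailer <- random_nt(u3, gc)
      main_start <- u5
      main_end <- u5 + 3L * (k + 1L)
      orfs <- tibble(transcript_id = id, type = "main",
                     start = main_start, end = main_end,
                     level = stats::rlnorm(1, 0, 1))
      # uORF planted wholly inside the leader
      if (runif(1) < uorf_prob) {
        ku_max <- min(uorf_codons[2], (u5 - 6L) %/% 3L - 1L)
        if (ku_max >= uorf_codons[1]) {
          ku <- sample_range(uorf_codons[1], ku_max)
          ulen <- 3L * (ku + 1L)
          uo <- sample_range(0L, u5 - ulen)
          useq <- random_orf(ku, gc)
          # re-randomise until no premature in-frame stop arises from
          # the leader context (none can: the ORF is self-contained)
          substr(leader, uo + 1L, uo + ulen) <- useq
          orfs <- bind_rows(orfs, tibble(
            transcript_id = id, type = "uORF",
            start = uo, end = uo + ulen,
            level = stats::rlnorm(1, -0.5, 0.75)
          ))
        }
      }
      seq <- paste0(leader, orf, trailer)
      # internal overlapping ORF in a shifted frame, by rejection
      if (runif(1) < overlap_prob && k >= 20L) {
        planted <- plant_internal_orf(seq, main_start, main_end, gc)
        if (!is.null(planted)) {
          seq <- planted$seq
          orfs <- bind_rows(orfs, tibble(
            transcript_id = id, type = "internal_overlapping",
            start = planted$start, end = planted$end,
            level = stats::rlnorm(1, -1, 0.5)
          ))
        }
      }
      tx_list[[i]] <- tibble(
        transcript_id = id, sequence = seq, length = nchar(seq),
        cds_start = main_start, cds_end = main_end, category = "mRNA"
      )
      orf_list[[i]] <- orfs
    }
    if (n_rrna > 0) {
      for (j in seq_len(n_rrna)) {
        id <- sprintf("rrna%02d", j)
        tx_list[[n_transcripts + j]] <- tibble(
          transcript_id = id, sequence = random_nt(rrna_length, gc + 0.05),
          length = rrna_length, cds_start = NA_integer_,
          cds_end = NA_integer_, category = "rRNA"
        )
      }
    }
    transcripts <- bind_rows(tx_list)
    orfs <- bind_rows(orf_list) %>%
      mutate(frame = .data$start %% 3L,
             orf_id = paste0(.data$transcript_id, ":", .data$start,
                             "-", .data$end)) %>%
      select("orf_id", "transcript_id", "type", "start", "end", "frame",
             "level")
    structure(
      list(transcripts = transcripts, orfs = orfs,
           rna_levels = tibble(
             transcript_id = transcripts$transcript_id,
             rna_level = ifelse(transcripts$category == "mRNA",
                                stats::rlnorm(nrow(transcripts), 0, 1), 0)
           ),
           seed = seed,
           config = list(n_transcripts = n_transcripts,
                         orf_codons = orf_codons, utr5 = utr5, utr3 = utr3,
                         gc = gc, uorf_prob = uorf_prob,
                         overlap_prob = overlap_prob, n_rrna = n_rrna)),
      class = "ribo_sim_truth"
    )
  })
}

# Plant an AUG..stop ORF in a shifted frame inside [main_start, main_end),
# keeping the main frame free of stop codons. Rejection sampling with a
# bounded number of attempts; NULL when no placement is found.
plant_internal_orf <- function(seq, main_start, main_end, gc,
                               attempts = 50L) {
  k_main <- (main_end - main_start) %/% 3L - 1L
  for (a in seq_len(attempts)) {
    kov <- sample_range(5L, 12L)
    ovlen <- 3L * (kov + 1L)
    shift <- sample_range(1L, 2L)
    # candidate start: in main frame + shift, fully inside the sense codons
    first_codon <- sample_range(2L, k_main - kov - 3L)
    ov_start <- main_start + 3L * first_codon + shift
    ov_end <- ov_start + ovlen
    if (ov_end > main_end - 3L) next
    cand <- seq
    substr(cand, ov_start + 1L, ov_end) <- random_orf(kov, gc)
    # affected main-frame codons must stay stop-free
    lo_c <- (ov_start - main_start) %/% 3L
    hi_c <- (ov_end - 1L - main_start) %/% 3L
    region <- substr(cand, main_start + 3L * lo_c + 1L,
                     main_start + 3L * (hi_c + 1L))
    cods <- substring(region, seq(1, nchar(region), 3L),
                      seq(3, nchar(region), 3L))
    if (any(cods %in% .codons$stops)) next
    return(list(seq = cand, start = ov_start, end = ov_end))
  }
  NULL
}

#' Simulate footprint and RNA-seq reads from known truth
#'
#' Places elongation footprints with the P-site uniform over the sense
#' codons of each translated ORF (weighted by the ORF's translation
#' level), up-weights the start codon by the preset's initiation pause
#' factor and the stop codon (A-site) by its termination pause factor,
#' draws each footprint's length class from the state's mixture, sets
#' the 5' end to `P-site first nt - L5` (elongation) or
#' `stop first nt - 3 - L5` (termination), and jitters it by +/-1 nt
#' with probability `(1 - fidelity)/2` per side. rRNA contaminant reads
#' are drawn uniformly from the rRNA transcripts; RNA-seq reads are
#' placed uniformly over transcripts in proportion to RNA abundance
#' times length (alkaline-fragmentation-like uniform coverage).
#'
#' @param truth A [make_transcriptome()] result.
#' @param preset A [geometry_preset()].
#' @param n_reads Number of footprint reads.
#' @param seed Integer seed.
#' @param rrna_fraction Fraction of footprint reads drawn from rRNA
#'   transcripts (0 when the truth has none).
#' @param n_rna Number of RNA-seq reads (0 to skip).
#' @param rna_length Range of RNA fragment lengths.
#' @param sample Sample label.
#' @return List `ribo`, `rna` of read tibbles (the `rna` element is an
#'   empty tibble when `n_rna = 0`).
#' @export
simulate_reads <- function(truth, preset, n_reads, seed,
                           rrna_fraction = 0.05, n_rna = 0L,
                           rna_length = c(25L, 35L), sample = "sample1") {
  if (n_reads <= 0) abort("n_reads must be positive")
  tx <- truth$transcripts
  rrna_ids <- tx$transcript_id[tx$category == "rRNA"]
  if (!length(rrna_ids)) rrna_fraction <- 0
  withr::with_seed(seed, {
    n_contam <- rbinom(1L, n_reads, rrna_fraction)
    n_mrna <- n_reads - n_contam
    ribo <- sim_footprints(truth, preset, n_mrna, sample)
    if (n_contam > 0) {
      contam <- sim_contaminants(tx, rrna_ids, preset, n_contam, sample)
      ribo <- bind_rows(ribo, contam)
    }
    ribo <- ribo %>% arrange(.data$transcript_id, .data$five_prime,
                             .data$length)
    rna <- empty_reads()
    if (n_rna > 0) {
      rna <- sim_rna(tx, truth$rna_levels, n_rna, rna_length, sample) %>%
        arrange(.data$transcript_id, .data$five_prime, .data$length)
    }
    list(ribo = ribo, rna = rna)
  })
}

empty_reads <- function() {
  tibble(transcript_id = character(), five_prime = integer(),
         length = integer(), sample = character(), weight = numeric(),
         read_seq = character())
}

sim_footprints <- function(truth, preset, n, sample_label) {
  if (n <= 0) return(empty_reads())
  tx <- truth$transcripts
  orfs <- truth$orfs %>%
    mutate(n_sense = (.data$end - .data$start) %/% 3L - 1L)
  ip <- preset$init_pause
  tp <- preset$term_pause
  orf_w <- orfs$level * (ip + (orfs$n_sense - 1L) + tp)
  oi <- sample.int(nrow(orfs), n, replace = TRUE, prob = orf_w)
  ns <- orfs$n_sense[oi]
  u <- runif(n) * (ip + (ns - 1L) + tp)
  is_init <- u < ip
  is_term <- u >= ip + (ns - 1L)
  codon <- ifelse(is_init, 0L,
                  ifelse(is_term, NA_integer_,
                         1L + as.integer(floor(u - ip))))
  state <- ifelse(is_term, "termination", "elongation")
  # if the preset has no termination classes, fall back to elongation
  # geometry at the last sense codon
  has_term <- any(preset$classes$state == "termination")
  if (!has_term) {
    codon[is_term] <- ns[is_term] - 1L
    state[is_term] <- "elongation"
    is_term[] <- FALSE
  }
  cls <- preset$classes
  pick_class <- function(st, m) {
    sub <- cls[cls$state == st, ]
    sub[sample.int(nrow(sub), m, replace = TRUE, prob = sub$weight), ]
  }
  len <- integer(n)
  L5 <- integer(n)
  idx_e <- which(state == "elongation")
  idx_t <- which(state == "termination")
  if (length(idx_e)) {
    pe <- pick_class("elongation", length(idx_e))
    len[idx_e] <- pe$length
    L5[idx_e] <- pe$L5
  }
  if (length(idx_t)) {
    pt <- pick_class("termination", length(idx_t))
    len[idx_t] <- pt$length
    L5[idx_t] <- pt$L5
  }
  p_first <- ifelse(is_term, orfs$end[oi] - 6L, orfs$start[oi] + 3L * codon)
  five <- p_first - L5
  f <- preset$fidelity
  jit <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                prob = c((1 - f) / 2, f, (1 - f) / 2))
  five <- five + jit
  tid <- orfs$transcript_id[oi]
  tlen <- tx$length[match(tid, tx$transcript_id)]
  ok <- five >= 0L & five + len <= tlen
  reads <- tibble(transcript_id = tid[ok], five_prime = five[ok],
                  length = len[ok], sample = sample_label, weight = 1)
  reads$read_seq <- substr(tx$sequence[match(reads$transcript_id,
                                             tx$transcript_id)],
                           reads$five_prime + 1L,
                           reads$five_prime + reads$length)
  reads
}

sim_contaminants <- function(tx, rrna_ids, preset, n, sample_label) {
  rtx <- tx[tx$transcript_id %in% rrna_ids, ]
  ti <- sample.int(nrow(rtx), n, replace = TRUE)
  cls <- preset$classes
  ci <- sample.int(nrow(cls), n, replace = TRUE, prob = cls$weight)
  len <- cls$length[ci]
  five <- as.integer(floor(runif(n) * (rtx$length[ti] - len + 1L)))
  tibble(transcript_id = rtx$transcript_id[ti], five_prime = five,
         length = len, sample = sample_label, weight = 1,
         read_seq = substr(rtx$sequence[ti], five + 1L, five + len))
}

sim_rna <- function(tx, rna_levels, n, rna_length, sample_label) {
  lev <- rna_levels$rna_level[match(tx$transcript_id,
                                    rna_levels$transcript_id)]
  lev[is.na(lev)] <- 0
  w <- lev * tx$length
  if (all(w == 0)) w <- tx$length
  ti <- sample.int(nrow(tx), n, replace = TRUE, prob = w)
  len <- sample(rna_length[1]:rna_length[2], n, replace = TRUE)
  len <- pmin(len, tx$length[ti])
  five <- as.integer(floor(runif(n) * (tx$length[ti] - len + 1L)))
  tibble(transcript_id = tx$transcript_id[ti], five_prime = five,
         length = len, sample = sample_label, weight = 1,
         read_seq = substr(tx$sequence[ti], five + 1L, five + len))
}

#' Binomial thinning of reads or species counts (depletion model)
#'
#' Each read survives a depletion treatment independently with the
#' survival probability of its class; species counts are thinned
#' binomially.
#'
#' @param x A read tibble or a [species_table()].
#' @param survival For reads: a scalar probability, a named vector of
#'   probabilities by transcript category (requires `transcripts`), or
#'   a function of the read tibble returning per-read probabilities.
#'   For species tables: a scalar or a function of the table returning
#'   per-species probabilities (applied to `count_b`).
#' @param seed Integer seed.
#' @param transcripts Transcript tibble (for category-based survival).
#' @param sample Optional new sample label for the thinned reads.
#' @return Thinned object of the same shape.
#' @export
simulate_depletion <- function(x, survival, seed, transcripts = NULL,
                               sample = NULL) {
  probs_of <- function(obj) {
    p <- if (is.function(survival)) {
      survival(obj)
    } else if (!is.null(names(survival))) {
      if (is.null(transcripts)) abort("category survival needs transcripts")
      cat <- transcripts$category[match(obj$transcript_id,
                                        transcripts$transcript_id)]
      unname(survival[cat])
    } else {
      rep(survival, nrow(obj))
    }
    p[is.na(p)] <- 1
    if (any(p < 0 | p > 1)) abort("survival probabilities must lie in [0, 1]")
    p
  }
  withr::with_seed(seed, {
    if (!is.null(x[["count_a"]])) {
      p <- probs_of(x)
      x$count_b <- rbinom(nrow(x), x$count_b, p)
      x
    } else {
      p <- probs_of(x)
      keep <- rbinom(nrow(x), round(x$weight), p)
      out <- x[keep > 0, ]
      out$weight <- keep[keep > 0]
      if (!is.null(sample)) out$sample <- sample
      out
    }
  })
}
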