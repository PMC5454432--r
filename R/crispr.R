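# CRISPR repeat-spacer arrays: seed-and-extend detection, orientation by
# the flanking repeat, ungapped spacer-to-protospacer matching with
# whole-spacer / 5'-half / seed identities, PAM detection, and immunity
# calls against observed infection outcomes.

#' Detect repeat-spacer arrays in a genome
#'
#' A CRT-style seed-and-extend detector: an exact `seed_len`-mer recurring at
#' a spacing compatible with one repeat plus one spacer nucleates a
#' candidate array, which is extended repeat by repeat and then column-wise
#' while at most `max_repeat_mismatch` of the copies disagree with the
#' majority base. Runs of at least `min_repeats` near-identical repeats with
#' in-range spacers are reported; the repeat consensus is the column
#' majority.
#'
#' @param genome a [genome_record()]
#' @param min_repeats minimum repeat copies per array
#' @param repeat_len allowed repeat length range (nt)
#' @param spacer_len allowed spacer length range (nt)
#' @param max_repeat_mismatch tolerated fraction of disagreeing copies per
#'   repeat column
#' @param seed_len exact seed length used for nucleation
#' @return list of arrays; each array is a list with host_id, start, end
#'   (0-based half-open), repeats and spacers data.frames, consensus,
#'   orientation ("forward" until oriented)
#' @export
detect_arrays <- function(genome, min_repeats = 3L, repeat_len = c(23L, 47L),
                          spacer_len = c(17L, 50L),
                          max_repeat_mismatch = 0.2, seed_len = 8L) {
  s <- genome$sequence
  G <- nchar(s)
  min_period <- repeat_len[1] + spacer_len[1]
  max_period <- repeat_len[2] + spacer_len[2]
  if (G < min_period + seed_len) return(list())
  ch <- seq_chars(s)
  kmers <- substring(s, 1:(G - seed_len + 1L), seed_len:G)
  pos_by_kmer <- split(seq_along(kmers), kmers)
  arrays <- list()
  i <- 1L
  while (i <= G - min_period - seed_len + 1L) {
    seed <- kmers[i]
    if (grepl("N", seed, fixed = TRUE)) { i <- i + 1L; next }
    cand <- pos_by_kmer[[seed]]
    nxt <- cand[cand - i >= min_period & cand - i <= max_period]
    if (!length(nxt)) { i <- i + 1L; next }
    starts <- c(i, nxt[1])
    repeat {
      last <- starts[length(starts)]
      cand2 <- pos_by_kmer[[seed]]
      nxt2 <- cand2[cand2 - last >= min_period & cand2 - last <= max_period]
      if (!length(nxt2)) break
      starts <- c(starts, nxt2[1])
    }
    if (length(starts) < min_repeats) { i <- i + 1L; next }
    periods <- diff(starts)
    max_rep <- min(repeat_len[2], min(periods) - spacer_len[1])
    allowed <- floor(max_repeat_mismatch * length(starts))
    agree <- function(off) {
      col <- ch[starts + off]
      tab <- table(col)
      length(starts) - max(tab) <= allowed
    }
    # extend right from the seed, then left
    right <- seed_len - 1L
    while (right + 1L < max_rep &&
           starts[length(starts)] + right + 1L <= G &&
           agree(right + 1L)) right <- right + 1L
    left <- 0L
    while (right - left + 2L <= max_rep && starts[1] - left - 1L >= 1L &&
           agree(-left - 1L)) left <- left + 1L
    r_starts <- starts - left
    rep_len <- right + left + 1L
    sp_lens <- diff(r_starts) - rep_len
    ok <- rep_len >= repeat_len[1] && rep_len <= repeat_len[2] &&
      all(sp_lens >= spacer_len[1] & sp_lens <= spacer_len[2])
    if (!ok) { i <- i + 1L; next }
    reps <- substring(s, r_starts, r_starts + rep_len - 1L)
    consensus <- paste(apply(do.call(rbind, strsplit(reps, "")), 2,
                             function(col) names(which.max(table(col)))),
                       collapse = "")
    sp_start <- r_starts[-length(r_starts)] + rep_len
    sp_end <- r_starts[-1] - 1L
    aid <- sprintf("%s_array%d", genome$id, length(arrays) + 1L)
    arrays[[length(arrays) + 1L]] <- list(
      array_id = aid, host_id = genome$id, location = genome$location,
      start = r_starts[1] - 1L, end = r_starts[length(r_starts)] + rep_len - 1L,
      repeats = data.frame(start = r_starts - 1L,
                           end = r_starts + rep_len - 1L,
                           sequence = reps, stringsAsFactors = FALSE),
      spacers = data.frame(
        spacer_id = sprintf("%s_sp%02d", aid, seq_along(sp_start)),
        index = seq_along(sp_start), start = sp_start - 1L, end = sp_end,
        sequence = substring(s, sp_start, sp_end), stringsAsFactors = FALSE),
      consensus = consensus, orientation = "forward")
    i <- r_starts[length(r_starts)] + rep_len
  }
  arrays
}

#' Orient an array's spacers by its repeat
#'
#' The array consensus repeat is compared (Hamming) to a reference repeat in
#' both orientations. When the reverse complement matches better, every
#' spacer is reverse-complemented and the array order reversed; equal scores
#' leave the orientation ambiguous and the spacers are emitted in both
#' orientations, flagged.
#'
#' @param array one array from [detect_arrays()]
#' @param reference_repeat reference repeat sequence (same length as the
#'   array consensus)
#' @return data.frame of oriented spacers: spacer_id, host_id, array_id,
#'   index, sequence (5'->3' crRNA orientation), orientation
#' @export
orient_spacers <- function(array, reference_repeat) {
  cons <- array$consensus
  if (nchar(reference_repeat) != nchar(cons))
    stop("reference repeat length ", nchar(reference_repeat),
         " incompatible with consensus length ", nchar(cons))
  d_fwd <- hamming(cons, toupper(reference_repeat))
  d_rev <- hamming(cons, revcomp(reference_repeat))
  sp <- array$spacers
  base <- data.frame(spacer_id = sp$spacer_id, host_id = array$host_id,
                     array_id = array$array_id, index = sp$index,
                     start = sp$start, end = sp$end,
                     sequence = sp$sequence, stringsAsFactors = FALSE)
  if (d_fwd < d_rev) {
    base$orientation <- "forward"
    return(base)
  }
  revd <- base[rev(seq_len(nrow(base))), , drop = FALSE]
  revd$sequence <- revcomp(revd$sequence)
  revd$index <- seq_len(nrow(revd))
  rownames(revd) <- NULL
  if (d_rev < d_fwd) {
    revd$orientation <- "reverse"
    return(revd)
  }
  base$orientation <- "ambiguous_forward"
  revd$orientation <- "ambiguous_reverse"
  revd$spacer_id <- paste0(revd$spacer_id, "_rc")
  rbind(base, revd)
}

longest_run <- function(x) {
  r <- rle(x)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

# collapse overlapping qualifying windows to local maxima (ties: leftmost)
collapse_windows <- function(starts, counts, L) {
  if (!length(starts)) return(integer(0))
  grp <- cumsum(c(1L, diff(starts) >= L))
  unlist(lapply(split(seq_along(starts), grp), function(ix) {
    ix[which.max(counts[ix])]
  }), use.names = FALSE)
}

#' Match one spacer against a viral genome
#'
#' Ungapped identity is computed for every window of spacer length on both
#' strands. A window is reported when its whole-spacer identity is strictly
#' greater than `report_threshold` and it contains an exact match run of at
#' least `min_anchor` bases — the word-hit requirement of BLASTN-style
#' spacer matching, without which an AT-rich 35 kb genome yields hundreds
#' of spurious >50% windows per spacer by composition alone. Overlapping
#' reported windows are collapsed to the local maximum. The 5'-half
#' identity covers the first ceil(L/2) spacer bases and the seed identity
#' the first `seed_len` (PAM-proximal) bases. N bases never count as
#' matches.
#'
#' @param spacer spacer sequence, 5'->3' crRNA orientation
#' @param virus a [genome_record()]
#' @param report_threshold report windows with identity > this (strict)
#' @param seed_len seed region length (PAM-proximal bases)
#' @param min_anchor minimum exact match run (nt) a reported window must
#'   contain; 0 disables anchoring
#' @return data.frame of matches: virus_id, start, end (0-based half-open),
#'   strand, full_identity, half5_identity, seed_identity
#' @export
match_spacer <- function(spacer, virus, report_threshold = 0.5,
                         seed_len = 8L, min_anchor = 12L) {
  spacer <- toupper(spacer)
  L <- nchar(spacer)
  G <- nchar(virus$sequence)
  empty <- data.frame(virus_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      full_identity = numeric(), half5_identity = numeric(),
                      seed_identity = numeric(), stringsAsFactors = FALSE)
  if (L > G) return(empty)
  sp_enc <- encode_dna(spacer)
  half_n <- ceiling(L / 2)
  seed_n <- min(seed_len, L)
  out <- list()
  sp_chars <- seq_chars(spacer)
  for (strand in c("+", "-")) {
    gseq <- if (strand == "+") virus$sequence else revcomp(virus$sequence)
    counts <- window_counts_c(sp_enc, encode_dna(gseq))
    qual <- which(counts / L > report_threshold)
    if (min_anchor > 0L && length(qual)) {
      anchored <- vapply(qual, function(w) {
        wc <- seq_chars(substr(gseq, w, w + L - 1L))
        longest_run(sp_chars == wc & wc %in% DNA_BASES) >= min_anchor
      }, logical(1))
      qual <- qual[anchored]
    }
    keep <- collapse_windows(qual, counts[qual], L)
    for (w in qual[keep]) {
      win <- substr(gseq, w, w + L - 1L)
      eq <- sp_chars == seq_chars(win) & seq_chars(win) %in% DNA_BASES
      s0 <- if (strand == "+") w - 1L else G - (w - 1L) - L
      out[[length(out) + 1L]] <- data.frame(
        virus_id = virus$id, start = s0, end = s0 + L, strand = strand,
        full_identity = mean(eq),
        half5_identity = mean(eq[seq_len(half_n)]),
        seed_identity = mean(eq[seq_len(seed_n)]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Detect a PAM next to a protospacer
#'
#' Reads the `nchar(motif)` bases immediately adjacent to the protospacer on
#' the configured side of the protospacer-containing strand and compares
#' them to the IUPAC motif. Out-of-bounds positions give `pam_present =
#' FALSE` with an empty observed sequence.
#'
#' @param match one row from [match_spacer()] (needs start, end, strand)
#' @param virus the matched [genome_record()]
#' @param motif IUPAC motif (default CCN, the conventional Sulfolobus
#'   type I-A PAM)
#' @param side "5prime" (default) or "3prime" of the protospacer
#' @return list(pam_present, pam_sequence)
#' @export
detect_pam <- function(match, virus, motif = "CCN", side = "5prime") {
  m <- nchar(motif)
  G <- nchar(virus$sequence)
  five_prime <- identical(side, "5prime")
  # on the protospacer strand, 5' of a plus-strand protospacer lies to the
  # genomic left; for a minus-strand protospacer it lies to the genomic right
  left_side <- xor(match$strand == "-", five_prime)
  if (left_side) {
    lo <- match$start - m; hi <- match$start
  } else {
    lo <- match$end; hi <- match$end + m
  }
  if (lo < 0L || hi > G) return(list(pam_present = FALSE, pam_sequence = ""))
  obs <- substr(virus$sequence, lo + 1L, hi)
  if (match$strand == "-") obs <- revcomp(obs)
  list(pam_present = iupac_match(obs, motif), pam_sequence = obs)
}

#' Match a table of spacers against a set of viruses
#'
#' Runs [match_spacer()] for every spacer x virus combination and annotates
#' every reported match with its PAM status.
#'
#' @param spacers data.frame from [orient_spacers()] (or with at least
#'   spacer_id, host_id, sequence)
#' @param viruses named list of [genome_record()]
#' @param report_threshold strict identity threshold for reporting
#' @param pam_motif,pam_side PAM configuration, see [detect_pam()]
#' @param seed_len seed region length
#' @param min_anchor minimum exact match run, see [match_spacer()]
#' @return data.frame of annotated matches
#' @export
match_all_spacers <- function(spacers, viruses, report_threshold = 0.5,
                              pam_motif = "CCN", pam_side = "5prime",
                              seed_len = 8L, min_anchor = 12L) {
  out <- list()
  for (i in seq_len(nrow(spacers))) {
    for (v in viruses) {
      m <- match_spacer(spacers$sequence[i], v, report_threshold, seed_len,
                        min_anchor)
      if (!nrow(m)) next
      pam <- lapply(seq_len(nrow(m)), function(k)
        detect_pam(m[k, ], v, pam_motif, pam_side))
      m$pam_present <- vapply(pam, `[[`, logical(1), "pam_present")
      m$pam_sequence <- vapply(pam, `[[`, character(1), "pam_sequence")
      m <- cbind(data.frame(spacer_id = spacers$spacer_id[i],
                            host_id = spacers$host_id[i],
                            stringsAsFactors = FALSE), m)
      out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out))
    return(data.frame(spacer_id = character(), host_id = character(),
                      virus_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      full_identity = numeric(), half5_identity = numeric(),
                      seed_identity = numeric(), pam_present = logical(),
                      pam_sequence = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predict immunity and reconcile with observed infection
#'
#' A host is predicted immune to a virus when at least one spacer match
#' exceeds `id_threshold` whole-spacer identity (and carries a PAM when
#' `require_pam`). Predictions are reconciled with the observed infection
#' outcomes: a predicted-immune pair that still clears at the low titer is
#' an anti-CRISPR candidate; a predicted-susceptible pair with no clearing
#' even at the high titer is a resistance candidate.
#'
#' @param matches data.frame from [match_all_spacers()]
#' @param host_ids,virus_ids the full host and virus universe to call
#' @param infection optional [read_infection_matrix()] data.frame
#' @param id_threshold strict whole-spacer identity threshold
#' @param require_pam require a PAM for a qualifying match
#' @return data.frame of class `immunity_calls`: one row per host x virus
#'   with match counts (per protospacer site and per distinct spacer), best
#'   identity, predicted, observed clearings and discordance
#' @export
call_immunity <- function(matches, host_ids, virus_ids, infection = NULL,
                          id_threshold = 0.5, require_pam = TRUE) {
  out <- list()
  for (h in host_ids) for (v in virus_ids) {
    m <- matches[matches$host_id == h & matches$virus_id == v, , drop = FALSE]
    qual <- m$full_identity > id_threshold
    qual_pam <- qual & m$pam_present
    eligible <- if (require_pam) qual_pam else qual
    row <- data.frame(
      host_id = h, virus_id = v,
      n_matches_with_pam = sum(qual_pam),
      n_matches_no_pam = sum(qual & !m$pam_present),
      n_spacers_matching = length(unique(m$spacer_id[eligible])),
      best_full_identity = if (nrow(m)) max(m$full_identity) else 0,
      predicted = if (any(eligible)) "immune" else "susceptible",
      stringsAsFactors = FALSE)
    if (!is.null(infection)) {
      obs <- infection[infection$host_id == h & infection$virus_id == v, ,
                       drop = FALSE]
      if (nrow(obs)) {
        cl <- setNames(obs$clearing, as.character(obs$titer))
        row$clearing_high <- unname(cl["high"])
        row$clearing_medium <- unname(cl["medium"])
        row$clearing_low <- unname(cl["low"])
        row$discordance <-
          if (row$predicted == "immune" && !is.na(cl["low"]) && cl["low"] > 0)
            "anti_crispr_candidate"
          else if (row$predicted == "susceptible" && !is.na(cl["high"]) &&
                   cl["high"] == 0)
            "resistance_candidate"
          else "concordant"
      } else {
        row$clearing_high <- row$clearing_medium <- row$clearing_low <- NA
        row$discordance <- NA_character_
      }
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("immunity_calls", "data.frame")
  res
}

#' @export
print.immunity_calls <- function(x, ...) {
  cat(sprintf("<immunity_calls> %d host x virus pairs: %d predicted immune",
              nrow(x), sum(x$predicted == "immune")))
  if ("discordance" %in% names(x)) {
    cat(sprintf(", %d anti-CRISPR candidates, %d resistance candidates",
                sum(x$discordance == "anti_crispr_candidate", na.rm = TRUE),
                sum(x$discordance == "resistance_candidate", na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}
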