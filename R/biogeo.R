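# Biogeographic summary statistics over spacer matches: per-location match
# fractions, identity distributions, and the partition of matches and
# matched base pairs across core / variable / non-coding genome regions.

# round half up at 1 decimal, the convention behind printed values
# like "29.4%"
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

dedupe_matches <- function(matches) {
  key <- paste(matches$spacer_id, matches$virus_id, matches$start,
               matches$strand)
  matches[!duplicated(key), , drop = FALSE]
}

#' Per-location spacer match fractions
#'
#' A spacer counts as matching when any reported match to any virus exceeds
#' the identity threshold. Fractions are reported per host location and per
#' location x virus; the per-spacer denominator is the total number of
#' spacers from that location.
#'
#' @param spacers oriented spacer table (spacer_id, host_id)
#' @param matches match table from [match_all_spacers()]
#' @param sample_sheet data.frame with host id -> location
#' @param threshold strict whole-spacer identity threshold
#' @return list with `by_location` and `by_location_virus` data.frames
#'   (n_spacers_total, n_spacers_matching, fraction, pct)
#' @export
match_fractions <- function(spacers, matches, sample_sheet,
                            threshold = 0.5) {
  loc <- sample_sheet$location[match(spacers$host_id, sample_sheet$id)]
  if (anyNA(loc))
    stop("spacer host not in sample sheet: ",
         spacers$host_id[which(is.na(loc))[1]])
  spacers$location <- loc
  matches <- dedupe_matches(matches)
  matches <- matches[matches$full_identity > threshold, , drop = FALSE]
  hit <- spacers$spacer_id %in% matches$spacer_id
  by_loc <- do.call(rbind, lapply(split(hit, spacers$location), function(h)
    data.frame(n_spacers_total = length(h), n_spacers_matching = sum(h))))
  by_loc <- data.frame(location = rownames(by_loc), by_loc,
                       row.names = NULL, stringsAsFactors = FALSE)
  by_loc$fraction <- by_loc$n_spacers_matching / by_loc$n_spacers_total
  by_loc$pct <- round_half_up(100 * by_loc$fraction)
  viruses <- sort(unique(matches$virus_id))
  rows <- list()
  for (l in unique(spacers$location)) for (v in viruses) {
    sp_l <- spacers$spacer_id[spacers$location == l]
    hit_v <- sp_l %in% matches$spacer_id[matches$virus_id == v]
    rows[[length(rows) + 1L]] <- data.frame(
      location = l, virus_id = v, n_spacers_total = length(sp_l),
      n_spacers_matching = sum(hit_v),
      fraction = sum(hit_v) / length(sp_l),
      pct = round_half_up(100 * sum(hit_v) / length(sp_l)),
      stringsAsFactors = FALSE)
  }
  by_lv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(location = character(), virus_id = character(),
               n_spacers_total = integer(), n_spacers_matching = integer(),
               fraction = numeric(), pct = numeric())
  list(by_location = by_loc, by_location_virus = by_lv)
}

#' Identity histogram per host location x virus
#'
#' Counts of reported matches (identity strictly above the threshold) per
#' identity bin of `bin_width` percentage points.
#'
#' @param matches match table from [match_all_spacers()]
#' @param sample_sheet host id -> location table
#' @param threshold strict identity threshold
#' @param bin_width bin width in percentage points
#' @return data.frame location, virus_id, bin_lo, bin_hi, n_matches
#' @export
identity_distribution <- function(matches, sample_sheet, threshold = 0.5,
                                  bin_width = 5) {
  matches <- dedupe_matches(matches)
  matches <- matches[matches$full_identity > threshold, , drop = FALSE]
  if (!nrow(matches))
    return(data.frame(location = character(), virus_id = character(),
                      bin_lo = numeric(), bin_hi = numeric(),
                      n_matches = integer()))
  loc <- sample_sheet$location[match(matches$host_id, sample_sheet$id)]
  pct <- 100 * matches$full_identity
  # bins are (lo, hi]; 100% falls in the top bin
  bin_hi <- pmax(ceiling(pct / bin_width), ceiling(100 * threshold /
                                                    bin_width) + 1L) *
    bin_width
  agg <- stats::aggregate(
    list(n_matches = rep(1L, nrow(matches))),
    by = list(location = loc, virus_id = matches$virus_id, bin_hi = bin_hi),
    FUN = sum)
  agg$bin_lo <- agg$bin_hi - bin_width
  agg[order(agg$location, agg$virus_id, agg$bin_lo),
      c("location", "virus_id", "bin_lo", "bin_hi", "n_matches")]
}

# core / variable / non-coding tiling of one genome; precedence
# core > variable where ORFs overlap, non-coding is everything else
region_tiling <- function(genome, pg) {
  G <- nchar(genome$sequence)
  m <- pg$membership[pg$membership$genome_id == genome$id, , drop = FALSE]
  o <- pg$orfs[match(m$orf_id, pg$orfs$orf_id), ]
  ir <- function(rows) {
    if (!nrow(rows)) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(start = rows$start + 1L, end = rows$end))
  }
  core <- ir(o[m$status == "core", , drop = FALSE])
  varr <- IRanges::setdiff(ir(o[m$status == "variable", , drop = FALSE]), core)
  nc <- IRanges::setdiff(IRanges::IRanges(1L, G),
                         IRanges::union(core, varr))
  list(core = core, variable = varr, non_coding = nc, genome_len = G)
}

#' Partition spacer matches across core, variable and non-coding regions
#'
#' Each reported match is assigned to the category containing the majority
#' of its protospacer bases (ties broken core > variable > non-coding); base
#' pair coverage is the union of reported protospacer intervals per category
#' divided by the category size.
#'
#' @param matches match table (already thresholded as reported)
#' @param genomes named list of matched [genome_record()]
#' @param pg a [pangenome()] result covering the matched viruses
#' @return data.frame, one row per virus: match counts and percentages per
#'   category, and per-category bp coverage fractions
#' @export
region_partition <- function(matches, genomes, pg) {
  matches <- dedupe_matches(matches)
  cats <- c("core", "variable", "non_coding")
  out <- list()
  for (vid in sort(unique(matches$virus_id))) {
    if (is.null(genomes[[vid]]))
      stop("matched virus lacks a genome record: ", vid)
    if (!vid %in% pg$membership$genome_id)
      stop("matched virus lacks cluster annotation: ", vid)
    til <- region_tiling(genomes[[vid]], pg)
    m <- matches[matches$virus_id == vid, , drop = FALSE]
    mr <- IRanges::IRanges(start = m$start + 1L, end = m$end)
    # per-match overlap totals per category
    bp <- sapply(cats, function(cc) {
      hits <- IRanges::findOverlaps(mr, til[[cc]])
      w <- integer(nrow(m))
      if (length(hits)) {
        pint <- IRanges::pintersect(mr[S4Vectors::queryHits(hits)],
                                    til[[cc]][S4Vectors::subjectHits(hits)])
        tw <- tapply(IRanges::width(pint), S4Vectors::queryHits(hits), sum)
        w[as.integer(names(tw))] <- as.integer(tw)
      }
      w
    })
    bp <- matrix(bp, nrow = nrow(m), dimnames = list(NULL, cats))
    assign_cat <- apply(bp, 1, function(w) cats[which.max(w)])
    counts <- table(factor(assign_cat, levels = cats))
    cov <- vapply(cats, function(cc) {
      denom <- sum(IRanges::width(til[[cc]]))
      if (denom == 0L) return(NA_real_)
      covered <- sum(IRanges::width(IRanges::intersect(
        IRanges::reduce(mr), til[[cc]])))
      covered / denom
    }, numeric(1))
    out[[vid]] <- data.frame(
      virus_id = vid, n_matches = nrow(m),
      n_core = as.integer(counts["core"]),
      n_variable = as.integer(counts["variable"]),
      n_non_coding = as.integer(counts["non_coding"]),
      pct_core = round_half_up(100 * counts["core"] / nrow(m)),
      pct_variable = round_half_up(100 * counts["variable"] / nrow(m)),
      pct_non_coding = round_half_up(100 * counts["non_coding"] / nrow(m)),
      cov_core = cov["core"], cov_variable = cov["variable"],
      cov_non_coding = cov["non_coding"], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
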