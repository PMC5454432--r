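# Within-cluster codon alignment, Nei-Gojobori Pn/Ps, Jukes-Cantor
# distances with complete deletion, and neighbor-joining trees.

GAP <- "-"
STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_split <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

aa_of <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

strip_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3L && substr(cds, n - 2L, n) %in% STOP_CODONS)
    substr(cds, 1L, n - 3L) else cds
}

profile_of <- function(rows, alphabet) {
  chars <- lapply(rows, seq_chars)
  L <- length(chars[[1]])
  prof <- matrix(0, nrow = length(alphabet), ncol = L,
                 dimnames = list(alphabet, NULL))
  for (ch in chars) {
    idx <- match(ch, alphabet)
    keep <- !is.na(idx)  # gaps carry no residue mass
    if (any(keep)) {
      t <- table(factor(idx[keep], levels = seq_along(alphabet)),
                 factor(which(keep), levels = seq_len(L)))
      prof <- prof + as.matrix(t)
    }
  }
  sweep(prof, 2, pmax(1, length(rows)), "/")
}

apply_moves <- function(rows, moves, consume) {
  # consume: 1 and the profile-own move advance this set of rows
  vapply(rows, function(r) {
    ch <- seq_chars(r)
    out <- character(length(moves))
    p <- 0L
    for (k in seq_along(moves)) {
      if (moves[k] %in% consume) { p <- p + 1L; out[k] <- ch[p] }
      else out[k] <- GAP
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Codon-aware alignment of a set of CDS
#'
#' The CDS are translated, the proteins aligned by progressive profile
#' Needleman-Wunsch (guide order: decreasing length, ties by name), and each
#' protein gap expanded to a codon gap, so every row ungaps back to its input
#' CDS. A trailing stop codon is removed first; an internal stop is an error.
#'
#' @param cds_set named character vector of in-frame CDS (>= 2)
#' @param params [alignment_params()]
#' @return object of class `codon_alignment`: list with `nuc` (aligned
#'   codon rows), `aa` (aligned protein rows), `ids`
#' @export
align_codons <- function(cds_set, params = alignment_params()) {
  stopifnot(length(cds_set) >= 2L, !is.null(names(cds_set)))
  cds_set <- vapply(cds_set, strip_stop, character(1))
  prots <- vapply(cds_set, translate_cds, character(1))
  if (any(grepl("*", prots, fixed = TRUE)))
    stop("internal stop codon in: ",
         names(prots)[grepl("*", prots, fixed = TRUE)][1])
  ord <- order(-nchar(prots), names(prots))
  aligned <- prots[ord[1]]
  for (i in ord[-1]) {
    profA <- profile_of(aligned, params$alphabet)
    profB <- profile_of(prots[i], params$alphabet)
    moves <- nw_profile_c(profA, profB, params$S,
                          params$gap_open, params$gap_extend)
    aligned <- c(apply_moves(aligned, moves, c(1L, 3L)),
                 apply_moves(prots[i], moves, c(1L, 2L)))
  }
  aligned <- aligned[names(cds_set)]
  nuc <- mapply(function(aa_row, cds) {
    codons <- codon_split(cds)
    ch <- seq_chars(aa_row)
    out <- character(length(ch))
    p <- 0L
    for (k in seq_along(ch)) {
      if (ch[k] == GAP) out[k] <- "---"
      else { p <- p + 1L; out[k] <- codons[p] }
    }
    paste(out, collapse = "")
  }, aligned, cds_set)
  structure(list(ids = names(cds_set), nuc = nuc, aa = aligned),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d sequences, %d codon columns\n",
              length(x$ids), nchar(x$nuc[[1]]) / 3L))
  invisible(x)
}

# ---- Nei-Gojobori machinery -------------------------------------------

# potential synonymous sites of one codon: at each position, the fraction of
# the 3 possible changes that are synonymous; stop-creating changes count as
# nonsynonymous, so s + n = 3 per codon
ng_sites <- function(codon) {
  aa0 <- aa_of(codon)
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    for (b in setdiff(DNA_BASES, base)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!(mut %in% STOP_CODONS) && identical(aa_of(mut), aa0)) s <- s + 1 / 3
    }
  }
  s
}

# average syn/nonsyn differences between two codons over all equally
# weighted single-step pathways; pathways through stop codons are excluded.
# Returns c(sd, nd) or NULL when every pathway is excluded.
ng_pathways <- function(ca, cb) {
  diff_pos <- which(seq_chars(ca) != seq_chars(cb))
  k <- length(diff_pos)
  if (k == 0L) return(c(0, 0))
  perms <- if (k == 1L) list(diff_pos) else {
    if (k == 2L) list(diff_pos, rev(diff_pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) diff_pos[i])
    }
  }
  tot <- c(0, 0)
  nvalid <- 0L
  for (path in perms) {
    cur <- ca
    sd <- 0; nd <- 0
    valid <- TRUE
    for (pos in path) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(cb, pos, pos)
      if (nxt %in% STOP_CODONS) { valid <- FALSE; break }
      if (identical(aa_of(cur), aa_of(nxt))) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (valid) { tot <- tot + c(sd, nd); nvalid <- nvalid + 1L }
  }
  if (nvalid == 0L) return(NULL)
  tot / nvalid
}

# memo caches: site counts and pathway results keyed by codon (pair)
ng_cache <- new.env(parent = emptyenv())

ng_sites_memo <- function(codon) {
  v <- ng_cache[[paste0("s", codon)]]
  if (is.null(v)) {
    v <- ng_sites(codon)
    ng_cache[[paste0("s", codon)]] <- v
  }
  v
}

ng_pathways_memo <- function(ca, cb) {
  key <- paste0("p", ca, cb)
  if (!is.null(ng_cache[[key]])) return(ng_cache[[key]])
  v <- ng_pathways(ca, cb)
  ng_cache[[key]] <- if (is.null(v)) NA else v
  if (is.null(v)) NA else v
}

#' Nei-Gojobori Pn/Ps for one aligned pair
#'
#' Potential synonymous (S) and nonsynonymous (N) sites are averaged over the
#' two sequences; observed differences are averaged over all equally weighted
#' single-step pathways, excluding pathways through stop codons. Codons
#' containing a gap or N in either row — and codon pairs whose pathways are
#' all excluded — are skipped.
#'
#' @param row_a,row_b codon-aligned nucleotide rows of equal length
#' @return data.frame with S, N, Sd, Nd, Ps, Pn, ratio, undefined,
#'   n_codons (compared codons)
#' @export
nei_gojobori_pair <- function(row_a, row_b) {
  stopifnot(nchar(row_a) == nchar(row_b), nchar(row_a) %% 3L == 0L)
  ca <- codon_split(toupper(row_a))
  cb <- codon_split(toupper(row_b))
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  S <- N <- Sd <- Nd <- 0
  n_codons <- 0L
  for (i in which(clean)) {
    d <- ng_pathways_memo(ca[i], cb[i])
    if (length(d) == 1L && is.na(d)) next  # all pathways hit a stop
    sa <- ng_sites_memo(ca[i])
    sb <- ng_sites_memo(cb[i])
    S <- S + (sa + sb) / 2
    N <- N + 3 - (sa + sb) / 2
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
    n_codons <- n_codons + 1L
  }
  if (n_codons == 0L)
    return(data.frame(S = NA_real_, N = NA_real_, Sd = NA_real_,
                      Nd = NA_real_, Ps = NA_real_, Pn = NA_real_,
                      ratio = NA_real_, undefined = TRUE, n_codons = 0L))
  Ps <- Sd / S
  Pn <- Nd / N
  undefined <- Ps == 0
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, Ps = Ps, Pn = Pn,
             ratio = if (undefined) NA_real_ else Pn / Ps,
             undefined = undefined, n_codons = n_codons)
}

#' Pooled Pn/Ps of a codon alignment
#'
#' Site and difference counts are summed over all unordered member pairs and
#' the ratio is taken on the pooled sums, (sum Nd / sum N) / (sum Sd / sum S)
#' — robust against division blow-ups on near-identical pairs.
#'
#' @param alignment a [align_codons()] result
#' @param min_members minimum members required (clusters below are skipped
#'   upstream; the published analysis used five)
#' @return one-row data.frame with pooled S, N, Sd, Nd, Ps, Pn, ratio,
#'   undefined, n_pairs
#' @export
cluster_pnps <- function(alignment, min_members = 2L) {
  ids <- alignment$ids
  if (length(ids) < min_members)
    stop("alignment has ", length(ids), " members; need >= ", min_members)
  S <- N <- Sd <- Nd <- 0
  n_pairs <- 0L
  for (i in seq_along(ids)[-length(ids)])
    for (j in seq((i + 1L), length(ids))) {
      r <- nei_gojobori_pair(alignment$nuc[[i]], alignment$nuc[[j]])
      if (r$n_codons == 0L) next
      S <- S + r$S; N <- N + r$N; Sd <- Sd + r$Sd; Nd <- Nd + r$Nd
      n_pairs <- n_pairs + 1L
    }
  if (n_pairs == 0L || S == 0)
    return(data.frame(S = S, N = N, Sd = Sd, Nd = Nd, Ps = NA_real_,
                      Pn = NA_real_, ratio = NA_real_, undefined = TRUE,
                      n_pairs = n_pairs))
  Ps <- Sd / S
  Pn <- Nd / N
  undefined <- Ps == 0
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, Ps = Ps, Pn = Pn,
             ratio = if (undefined) NA_real_ else Pn / Ps,
             undefined = undefined, n_pairs = n_pairs)
}

# ---- Jukes-Cantor and neighbor joining --------------------------------

#' Jukes-Cantor distance from a proportion of differing sites
#'
#' `d = -(3/4) ln(1 - 4p/3)`; p >= 0.75 is saturated and reported as Inf.
#'
#' @param p proportion of differing sites in \\[0, 1\\]
#' @return distance (substitutions/site), Inf when saturated
#' @export
jc_from_p <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p >= 0.75, Inf, -0.75 * log(1 - 4 * p / 3))
}

#' Jukes-Cantor distance matrix with complete deletion
#'
#' Columns containing a gap or N in any row of the alignment are removed
#' first (complete deletion across the whole alignment, the MEGA setting
#' "all positions containing gaps and missing data were eliminated"); each
#' pair's p is then the mismatch fraction over the retained columns.
#'
#' @param rows named character vector of aligned nucleotide rows
#' @return symmetric matrix of distances with attribute `model = "JC"` and
#'   `n_sites` (columns retained)
#' @export
jc_matrix <- function(rows) {
  stopifnot(length(rows) >= 2L, !is.null(names(rows)))
  chars <- do.call(rbind, lapply(rows, seq_chars))
  keep <- apply(chars, 2, function(col) all(col %in% DNA_BASES))
  chars <- chars[, keep, drop = FALSE]
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  if (ncol(chars) == 0L) stop("complete deletion removed every column")
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n)) {
      p <- mean(chars[i, ] != chars[j, ])
      d[i, j] <- d[j, i] <- jc_from_p(p)
    }
  attr(d, "model") <- "JC"
  attr(d, "n_sites") <- ncol(chars)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape) on a symmetric matrix; taxa are
#' ordered by id first so ties resolve deterministically, and negative branch
#' lengths are clamped to zero.
#'
#' @param d symmetric numeric matrix with zero diagonal
#' @return an `ape::phylo` tree
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L)
  if (!isSymmetric(unname(d), tol = 1e-9)) stop("distance matrix is not symmetric")
  if (any(!is.finite(d))) stop("non-finite (saturated) distances in matrix")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Concatenated core-gene alignment
#'
#' Aligns every core cluster with exactly one member per genome and
#' concatenates the rows genome-wise — the alignment behind the core-genome
#' phylogeny.
#'
#' @param pg a [pangenome()] result
#' @param params [alignment_params()]
#' @return named character vector of concatenated aligned rows (one per
#'   genome), with attribute `n_clusters`
#' @export
concat_core_alignment <- function(pg, params = alignment_params()) {
  gids <- colnames(pg$pa)
  core <- names(pg$status)[pg$status == "core"]
  rows <- setNames(rep("", length(gids)), gids)
  used <- 0L
  for (cid in core) {
    members <- pg$clusters[[cid]]
    m <- pg$orfs[match(members, pg$orfs$orf_id), ]
    if (!setequal(m$genome_id, gids) || anyDuplicated(m$genome_id)) next
    cds <- setNames(m$cds, m$genome_id)[gids]
    aln <- align_codons(cds, params)
    rows <- paste0(rows, unname(aln$nuc[gids]))
    names(rows) <- gids
    used <- used + 1L
  }
  if (used == 0L) stop("no single-copy core clusters to concatenate")
  attr(rows, "n_clusters") <- used
  rows
}

#' Pn/Ps for every cluster above a size threshold
#'
#' @param pg a [pangenome()] result
#' @param min_members minimum cluster size (the published analysis aligned
#'   clusters with five or more members)
#' @param params [alignment_params()]
#' @return data.frame of pooled Pn/Ps rows, one per qualifying cluster
#' @export
pangenome_pnps <- function(pg, min_members = 5L,
                           params = alignment_params()) {
  out <- list()
  for (cid in names(pg$clusters)) {
    members <- pg$clusters[[cid]]
    if (length(members) < min_members) next
    m <- pg$orfs[match(members, pg$orfs$orf_id), ]
    cds <- setNames(m$cds, m$orf_id)
    aln <- align_codons(cds, params)
    r <- cluster_pnps(aln)
    r <- cbind(data.frame(cluster_id = cid,
                          status = unname(pg$status[cid]),
                          n_members = length(members)), r)
    out[[cid]] <- r
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = character(), status = character(),
               n_members = integer(), S = numeric(), N = numeric(),
               Sd = numeric(), Nd = numeric(), Ps = numeric(),
               Pn = numeric(), ratio = numeric(), undefined = logical(),
               n_pairs = integer())
  rownames(res) <- NULL
  res
}
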