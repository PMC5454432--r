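# Homologous gene clustering: all-vs-all Smith-Waterman on ORF proteins,
# Karlin-Altschul bit scores, a bit-score-ratio screen, Markov clustering,
# six-frame rescue of missed ORFs, and the core/variable partition.

#' Alignment parameters
#'
#' Scoring parameters for protein alignment and Karlin-Altschul bit-score
#' conversion. Defaults are the standard gapped BLOSUM62/11-1 constants
#' (lambda = 0.267, K = 0.041); they shift all bit scores jointly and largely
#' cancel in the bit-score ratio. The ambiguous residue X scores 0 against
#' every residue.
#'
#' @param matrix substitution matrix name (only "BLOSUM62" is shipped)
#' @param gap_open,gap_extend affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`
#' @param lambda,k Karlin-Altschul scale and constant
#' @return object of class `alignment_params`
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 11,
                             gap_extend = 1, lambda = 0.267, k = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, k > 0)
  if (matrix != "BLOSUM62") stop("unsupported substitution matrix: ", matrix)
  S <- blosum62_neutral_x()
  structure(list(matrix_name = matrix, S = S, alphabet = rownames(S),
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, k = k),
            class = "alignment_params")
}

#' Optimal local alignment score
#'
#' Exact affine-gap Smith-Waterman between two protein sequences.
#'
#' @param a,b amino-acid strings
#' @param params [alignment_params()]
#' @return raw alignment score (0 when nothing scores positively)
#' @export
local_align <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("local_align: empty sequence")
  sw_score_c(encode_protein(a, params$alphabet),
             encode_protein(b, params$alphabet),
             params$S, params$gap_open, params$gap_extend)
}

#' Karlin-Altschul bit score
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw_score raw alignment score (>= 0)
#' @param params [alignment_params()]
#' @return bit score
#' @export
bit_score <- function(raw_score, params = alignment_params()) {
  stopifnot(all(raw_score >= 0))
  (params$lambda * raw_score - log(params$k)) / log(2)
}

#' Extract ORFs from annotated genomes
#'
#' One ORF per CDS feature; minus-strand CDS are reverse-complemented before
#' translation, and a trailing stop codon is dropped. CDS whose length is not
#' a multiple of 3 are an error; CDS translating with an internal stop are
#' excluded from clustering but reported in the `excluded` attribute.
#'
#' @param genome a [genome_record()] with CDS features
#' @return data.frame with columns orf_id, genome_id, start, end, strand,
#'   cds (nucleotide), protein; attribute `excluded` lists flagged CDS
#' @export
extract_orfs <- function(genome) {
  f <- genome$features
  f <- f[f$kind == "CDS", , drop = FALSE]
  out <- list()
  excl <- list()
  for (i in seq_len(nrow(f))) {
    cds <- substr(genome$sequence, f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") cds <- revcomp(cds)
    if (nchar(cds) %% 3L != 0L)
      stop("CDS '", f$feature_id[i], "' in genome '", genome$id,
           "': length ", nchar(cds), " is not a multiple of 3")
    prot <- translate_cds(cds)
    row <- data.frame(orf_id = f$feature_id[i], genome_id = genome$id,
                      start = f$start[i], end = f$end[i],
                      strand = f$strand[i], cds = cds, protein = prot,
                      stringsAsFactors = FALSE)
    if (grepl("*", prot, fixed = TRUE)) excl[[length(excl) + 1L]] <- row
    else out[[length(out) + 1L]] <- row
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(orf_id = character(), genome_id = character(),
               start = integer(), end = integer(), strand = character(),
               cds = character(), protein = character(),
               stringsAsFactors = FALSE)
  attr(res, "excluded") <- if (length(excl)) do.call(rbind, excl) else NULL
  res
}

#' Naive fallback ORF finder
#'
#' For FASTA-only input: in each of the six frames, every stop-to-stop
#' segment contributes its longest ORF of at least `min_codons` codons
#' starting at ATG/GTG/TTG.
#'
#' @param genome a [genome_record()]
#' @param min_codons minimum ORF length in codons (start included)
#' @return ORF data.frame as in [extract_orfs()]
#' @export
naive_orfs <- function(genome, min_codons = 60L) {
  G <- nchar(genome$sequence)
  rows <- list()
  n <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    for (frame in 0:2) {
      len <- (nchar(s) - frame) %/% 3L
      if (len < min_codons) next
      codons <- substring(s, frame + seq(1L, by = 3L, length.out = len),
                          frame + seq(3L, by = 3L, length.out = len))
      stops <- which(codons %in% c("TAA", "TAG", "TGA"))
      bounds <- c(0L, stops, len + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        seg <- seq(bounds[b] + 1L, length.out = bounds[b + 1L] - bounds[b] - 1L)
        if (length(seg) < min_codons) next
        starts <- seg[codons[seg] %in% c("ATG", "GTG", "TTG")]
        if (!length(starts)) next
        st <- starts[1]  # earliest start = longest ORF in the segment
        last <- bounds[b + 1L]
        if (last > len) last <- len + 1L  # no stop: run to frame end
        ncod <- last - st
        if (ncod < min_codons) next
        # coordinates on the scanned strand, then mapped to the genome
        a <- frame + (st - 1L) * 3L          # 0-based start on strand
        stop_extra <- if (last <= len) 3L else 0L
        bnd <- frame + (last - 1L) * 3L + stop_extra
        if (strand == "+") { g0 <- a; g1 <- bnd } else {
          g0 <- G - bnd; g1 <- G - a
        }
        n <- n + 1L
        cds <- substr(s, a + 1L, bnd)
        rows[[n]] <- data.frame(
          orf_id = sprintf("%s_orf%03d", genome$id, n),
          genome_id = genome$id, start = g0, end = g1, strand = strand,
          cds = cds, protein = translate_cds(cds), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(extract_orfs(genome))  # empty frame
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' All-vs-all similarity graph with a bit-score-ratio screen
#'
#' Every ORF pair is aligned by Smith-Waterman; the edge weight is the
#' alignment bit score divided by the smaller of the two self-alignment bit
#' scores, a length-normalized similarity in \\[0, 1\\]. Edges with ratio
#' below `ratio_threshold` are dropped ("0.3 or higher" is the screen used
#' for SIRV clusters).
#'
#' @param orfs ORF data.frame from [extract_orfs()] (rows from all genomes)
#' @param params [alignment_params()]
#' @param ratio_threshold minimum bit-score ratio for an edge (kept iff
#'   ratio >= threshold)
#' @return data.frame orf_a, orf_b, raw_score, bits, ratio, plus attribute
#'   `self_bits` (named vector of self-alignment bit scores)
#' @export
build_similarity_graph <- function(orfs, params = alignment_params(),
                                   ratio_threshold = 0.3) {
  stopifnot(nrow(orfs) >= 2L)
  enc <- lapply(orfs$protein, encode_protein, alphabet = params$alphabet)
  raw <- sw_allpairs_c(enc, params$S, params$gap_open, params$gap_extend)
  bits <- bit_score(raw, params)
  self <- diag(bits)
  names(self) <- orfs$orf_id
  n <- nrow(orfs)
  idx <- which(upper.tri(raw), arr.ind = TRUE)
  ratio <- bits[idx] / pmin(self[idx[, 1]], self[idx[, 2]])
  keep <- ratio >= ratio_threshold
  edges <- data.frame(orf_a = orfs$orf_id[idx[keep, 1]],
                      orf_b = orfs$orf_id[idx[keep, 2]],
                      raw_score = raw[idx][keep],
                      bits = bits[idx][keep],
                      ratio = ratio[keep], stringsAsFactors = FALSE)
  attr(edges, "self_bits") <- self
  edges
}

#' Markov clustering of a weighted similarity graph
#'
#' Column-stochastic iteration of expansion (matrix squaring) and inflation
#' (elementwise power then renormalization) on the ratio-weighted graph with
#' self-loops (weight = maximum incident edge weight), until the maximum
#' column change falls below `tol`. Clusters are the weakly connected
#' components of the attractor graph; nodes without edges become singletons.
#'
#' @param edges data.frame with orf_a, orf_b and weight column `ratio`
#' @param nodes character vector of all node ids (covers isolated nodes)
#' @param inflation inflation exponent
#' @param max_iter,tol iteration controls
#' @param prune entries below this are zeroed each iteration
#' @return list of character vectors (cluster member ids), with attribute
#'   `converged`
#' @export
mcl_cluster <- function(edges, nodes, inflation = 2, max_iter = 100L,
                        tol = 1e-6, prune = 1e-8) {
  n <- length(nodes)
  stopifnot(n >= 1L)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    ia <- match(edges$orf_a, nodes)
    ib <- match(edges$orf_b, nodes)
    if (anyNA(ia) || anyNA(ib)) stop("edge references unknown node")
    A[cbind(ia, ib)] <- pmax(A[cbind(ia, ib)], edges$ratio)
    A[cbind(ib, ia)] <- pmax(A[cbind(ib, ia)], edges$ratio)
  }
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter, " iterations")
  adj <- (M >= tol) | (t(M) >= tol)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  out <- split(nodes, comp)
  names(out) <- NULL
  attr(out, "converged") <- converged
  out
}

# deterministic c1..cN ids: by decreasing size, then smallest member id
order_clusters <- function(members) {
  sizes <- lengths(members)
  firsts <- vapply(members, function(m) sort(m)[1], character(1))
  members[order(-sizes, firsts)]
}

#' Six-frame protein segments of a genome
#'
#' Translations of all six frames, split at stop codons; used for
#' TBLASTN-style rescue of unannotated ORFs.
#'
#' @param genome a [genome_record()]
#' @param min_aa minimum segment length reported
#' @return data.frame segment, strand, frame, aa_start (0-based within the
#'   frame translation)
#' @keywords internal
six_frame_segments <- function(genome, min_aa = 15L) {
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    for (frame in 0:2) {
      len <- (nchar(s) - frame) %/% 3L
      if (len < min_aa) next
      aa <- translate_cds(substr(s, frame + 1L, frame + len * 3L))
      if (nchar(aa) < len) aa <- paste0(aa, "*")  # trailing stop restored
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 0L
      for (p in parts) {
        if (nchar(p) >= min_aa)
          rows[[length(rows) + 1L]] <- data.frame(
            segment = p, strand = strand, frame = frame, aa_start = pos,
            stringsAsFactors = FALSE)
        pos <- pos + nchar(p) + 1L
      }
    }
  }
  if (!length(rows))
    return(data.frame(segment = character(), strand = character(),
                      frame = integer(), aa_start = integer()))
  do.call(rbind, rows)
}

#' Rescue cluster members missed by the annotation
#'
#' For every cluster x genome cell that is absent, each member protein is
#' locally aligned against all six translated frames of that genome
#' (TBLASTN-style). A hit whose bit score reaches `ratio_threshold` times the
#' member's self-alignment bit score upgrades the cell: to `present` when the
#' member protein occurs verbatim downstream of an in-frame ATG/GTG/TTG
#' start, otherwise to `present_no_start`.
#'
#' @param clusters list of member-id vectors (ordered c1..cN)
#' @param orfs ORF table covering all members
#' @param genomes named list of [genome_record()]
#' @param params [alignment_params()]
#' @param ratio_threshold minimum bit-score ratio for a rescue hit
#' @return presence/absence matrix (clusters x genomes) with entries
#'   "absent", "present", "present_no_start", "multi_copy"
#' @export
rescue_missed_orfs <- function(clusters, orfs, genomes,
                               params = alignment_params(),
                               ratio_threshold = 0.3) {
  pa <- presence_absence(clusters, orfs, names(genomes))
  frames <- lapply(genomes, six_frame_segments)
  enc_frames <- lapply(frames, function(f)
    lapply(f$segment, encode_protein, alphabet = params$alphabet))
  for (ci in seq_along(clusters)) {
    absent <- colnames(pa)[pa[ci, ] == "absent"]
    if (!length(absent)) next
    prots <- orfs$protein[match(clusters[[ci]], orfs$orf_id)]
    for (gid in absent) {
      segs <- frames[[gid]]
      if (!nrow(segs)) next
      hit <- "absent"
      for (p in prots) {
        self_bits <- bit_score(local_align(p, p, params), params)
        sc <- sw_many_c(encode_protein(p, params$alphabet),
                        enc_frames[[gid]], params$S,
                        params$gap_open, params$gap_extend)
        ratios <- bit_score(sc, params) / self_bits
        ok <- which(ratios >= ratio_threshold)
        if (!length(ok)) next
        hit <- "present_no_start"
        # verbatim copy reachable from an in-frame start -> genuine ORF
        for (si in ok) {
          at <- regexpr(p, segs$segment[si], fixed = TRUE)
          if (at > 0 && grepl("[MVL]", substr(segs$segment[si], 1L, at))) {
            hit <- "present"
            break
          }
        }
        if (hit == "present") break
      }
      pa[ci, gid] <- hit
    }
  }
  pa
}

presence_absence <- function(clusters, orfs, genome_ids) {
  pa <- matrix("absent", nrow = length(clusters), ncol = length(genome_ids),
               dimnames = list(paste0("c", seq_along(clusters)), genome_ids))
  for (ci in seq_along(clusters)) {
    g <- orfs$genome_id[match(clusters[[ci]], orfs$orf_id)]
    tab <- table(g)
    pa[ci, names(tab)[tab == 1L]] <- "present"
    pa[ci, names(tab)[tab > 1L]] <- "multi_copy"
  }
  pa
}

#' Core/variable partition of gene clusters
#'
#' A cluster is core when it is present (including rescued hits) in every
#' genome; otherwise it is variable. Per-genome core fractions are reported
#' as core ORFs / total ORFs.
#'
#' @param pa presence/absence matrix from [rescue_missed_orfs()] or
#'   `presence_absence()`
#' @param clusters list of member-id vectors aligned with `pa` rows
#' @param orfs ORF table
#' @return list with `status` (named character), `core_stats` data.frame
#' @export
partition_core_variable <- function(pa, clusters, orfs) {
  core <- apply(pa != "absent", 1, all)
  status <- ifelse(core, "core", "variable")
  names(status) <- rownames(pa)
  member_cluster <- rep(names(status), lengths(clusters))
  names(member_cluster) <- unlist(clusters)
  orf_status <- status[member_cluster[orfs$orf_id]]
  cs <- do.call(rbind, lapply(split(orf_status, orfs$genome_id), function(s)
    data.frame(n_orfs = length(s), n_core_orfs = sum(s == "core"),
               core_fraction = sum(s == "core") / length(s))))
  cs <- data.frame(genome_id = rownames(cs), cs, row.names = NULL,
                   stringsAsFactors = FALSE)
  list(status = status, core_stats = cs)
}

#' Build the pangenome of a set of annotated genomes
#'
#' The full clustering stage: ORF extraction, all-vs-all Smith-Waterman with
#' the bit-score-ratio screen, Markov clustering, optional six-frame rescue
#' of missed ORFs, and the core/variable partition.
#'
#' @param genomes named list of [genome_record()] with CDS features
#' @param params [alignment_params()]
#' @param ratio_threshold bit-score-ratio screen (edges kept iff >= this)
#' @param inflation MCL inflation
#' @param rescue run the six-frame rescue step
#' @param fallback_orfs call ORFs naively when a genome has no CDS features
#' @return object of class `sirv_pangenome`: orfs, edges, clusters (member
#'   lists), membership (orf -> cluster data.frame), status, pa and
#'   pa_pre_rescue matrices, core_stats, settings
#' @export
pangenome <- function(genomes, params = alignment_params(),
                      ratio_threshold = 0.3, inflation = 2,
                      rescue = TRUE, fallback_orfs = FALSE) {
  stopifnot(length(genomes) >= 2L)
  orfs <- do.call(rbind, lapply(genomes, function(g) {
    o <- extract_orfs(g)
    if (!nrow(o) && fallback_orfs) o <- naive_orfs(g)
    o
  }))
  rownames(orfs) <- NULL
  if (nrow(orfs) < 2L) stop("fewer than 2 ORFs across all genomes")
  edges <- build_similarity_graph(orfs, params, ratio_threshold)
  clusters <- mcl_cluster(edges, orfs$orf_id, inflation = inflation)
  converged <- attr(clusters, "converged")
  clusters <- order_clusters(clusters)
  names(clusters) <- paste0("c", seq_along(clusters))
  pa_pre <- presence_absence(clusters, orfs, names(genomes))
  pa <- if (rescue)
    rescue_missed_orfs(clusters, orfs, genomes, params, ratio_threshold)
  else pa_pre
  part <- partition_core_variable(pa, clusters, orfs)
  membership <- data.frame(
    orf_id = unlist(clusters, use.names = FALSE),
    genome_id = orfs$genome_id[match(unlist(clusters), orfs$orf_id)],
    cluster_id = rep(names(clusters), lengths(clusters)),
    status = part$status[rep(names(clusters), lengths(clusters))],
    stringsAsFactors = FALSE)
  rownames(membership) <- NULL
  structure(list(orfs = orfs, edges = edges, clusters = clusters,
                 membership = membership, status = part$status,
                 pa = pa, pa_pre_rescue = pa_pre,
                 core_stats = part$core_stats,
                 settings = list(ratio_threshold = ratio_threshold,
                                 inflation = inflation, rescue = rescue),
                 mcl_converged = converged),
            class = "sirv_pangenome")
}

#' @export
print.sirv_pangenome <- function(x, ...) {
  cat(sprintf(paste0("<sirv_pangenome> %d genomes, %d ORFs -> %d clusters ",
                     "(%d core, %d variable)\n"),
              ncol(x$pa), nrow(x$orfs), length(x$clusters),
              sum(x$status == "core"), sum(x$status == "variable")))
  invisible(x)
}

#' @method summary sirv_pangenome
#' @export
summary.sirv_pangenome <- function(object, ...) {
  print(object)
  cat("\nPer-genome core fraction (core ORFs / total ORFs):\n")
  print(object$core_stats, row.names = FALSE)
  cat(sprintf("\nBit-score-ratio screen >= %.2f; MCL inflation %.1f%s\n",
              object$settings$ratio_threshold, object$settings$inflation,
              if (object$settings$rescue) "; six-frame rescue applied" else ""))
  invisible(object)
}
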