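# Independent oracles used by the tests. Each is a deliberately plain
# implementation, kept separate from the package's code paths.

# full-matrix affine Smith-Waterman (gap of length k costs open + k*extend)
sw_oracle <- function(a, b, S, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + S[a[i - 1], b[j - 1]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# global affine NW score by exhaustive recursion (tiny inputs only)
nw_oracle <- function(a, b, S, open = 11, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  # state: position i in a, j in b, mode 0 diag / 1 gap-in-a / 2 gap-in-b
  rec <- function(i, j, mode) {
    key <- paste(i, j, mode)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, S[a[i], b[j]] + rec(i + 1, j + 1, 0))
    if (j <= length(b))  # gap in a
      best <- max(best, -(if (mode == 1) ext else open + ext) +
                    rec(i, j + 1, 1))
    if (i <= length(a))  # gap in b
      best <- max(best, -(if (mode == 2) ext else open + ext) +
                    rec(i + 1, j, 2))
    memo[[key]] <- best
    best
  }
  rec(1, 1, 0)
}

# score of an existing global pairwise alignment under the same gap model
alignment_score <- function(row_a, row_b, S, open = 11, ext = 1) {
  a <- strsplit(row_a, "")[[1]]
  b <- strsplit(row_b, "")[[1]]
  sc <- 0
  gap_a <- FALSE; gap_b <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" && b[k] == "-") next
    if (a[k] == "-") {
      sc <- sc - (if (gap_a) ext else open + ext)
      gap_a <- TRUE; gap_b <- FALSE
    } else if (b[k] == "-") {
      sc <- sc - (if (gap_b) ext else open + ext)
      gap_b <- TRUE; gap_a <- FALSE
    } else {
      sc <- sc + S[a[k], b[k]]
      gap_a <- gap_b <- FALSE
    }
  }
  sc
}

GC3 <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(GC3)[GC3 == "*"]

# Nei-Gojobori potential synonymous sites of one codon (independent code)
ng_sites_oracle <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == ch[pos]) next
    mut <- ch; mut[pos] <- b
    mut <- paste(mut, collapse = "")
    if (!(mut %in% ORACLE_STOPS) && GC3[[mut]] == GC3[[codon]])
      s <- s + 1 / 3
  }
  s
}

# pathway-averaged syn/nonsyn differences via explicit permutation listing
ng_diff_oracle <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  dp <- which(a != b)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perm_list(v[-k])) out <- c(out, list(c(v[k], rest)))
    out
  }
  tot <- c(0, 0); nok <- 0
  for (path in perm_list(dp)) {
    cur <- a; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in path) {
      nxt <- cur; nxt[pos] <- b[pos]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (c2 %in% ORACLE_STOPS) { ok <- FALSE; break }
      if (GC3[[c1]] == GC3[[c2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + c(sd, nd); nok <- nok + 1 }
  }
  if (nok == 0) return(NULL)
  c(sd = tot[1] / nok, nd = tot[2] / nok)
}

random_codon <- function() {
  repeat {
    cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")
    if (!(cod %in% ORACLE_STOPS)) return(cod)
  }
}

random_cds <- function(n_codons) {
  paste(replicate(n_codons, random_codon()), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n,
               replace = TRUE), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# step-by-step Markov-clustering oracle, written directly from the
# expansion/inflation description
mcl_oracle <- function(edges, nodes, inflation = 2, max_iter = 100,
                       tol = 1e-6, prune = 1e-8) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$orf_a[r], nodes); j <- match(edges$orf_b[r], nodes)
    A[i, j] <- max(A[i, j], edges$ratio[r])
    A[j, i] <- max(A[j, i], edges$ratio[r])
  }
  for (j in seq_len(n)) A[j, j] <- if (max(A[, j]) > 0) max(A[, j]) else 1
  M <- A %*% diag(1 / colSums(A), n)
  for (it in seq_len(max_iter)) {
    M2 <- (M %*% M)^inflation
    M2[M2 < prune] <- 0
    M2 <- M2 %*% diag(1 / colSums(M2), n)
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  reach <- (M >= tol) | (t(M) >= tol)
  # components by repeated breadth-first search
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    q <- s; comp <- integer(0)
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      q <- c(q, which(reach[v, ] & !seen))
    }
    comps[[length(comps) + 1]] <- sort(nodes[comp])
  }
  comps
}

canon_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, `[`, character(1), 1))]
}

# brute-force spacer-window oracle: every window, both strands, substring
# comparison, threshold strict, optional exact-run anchor
window_oracle <- function(spacer, genome_seq, threshold = 0.5,
                          min_anchor = 0) {
  L <- nchar(spacer)
  sp <- strsplit(spacer, "")[[1]]
  out <- list()
  G <- nchar(genome_seq)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }
  for (strand in c("+", "-")) {
    g <- if (strand == "+") genome_seq else rc(genome_seq)
    for (w in seq_len(G - L + 1)) {
      win <- strsplit(substr(g, w, w + L - 1), "")[[1]]
      eq <- sp == win & win %in% c("A", "C", "G", "T")
      if (mean(eq) <= threshold) next
      if (min_anchor > 0) {
        r <- rle(eq)
        run <- if (any(r$values)) max(r$lengths[r$values]) else 0
        if (run < min_anchor) next
      }
      s0 <- if (strand == "+") w - 1 else G - (w - 1) - L
      out[[length(out) + 1]] <- data.frame(start = s0, strand = strand,
                                           full_identity = mean(eq))
    }
  }
  if (!length(out)) return(data.frame(start = integer(),
                                      strand = character(),
                                      full_identity = numeric()))
  do.call(rbind, out)
}

# small, fast simulation settings used across tests
tiny_sim <- function(seed = 1, ...) {
  sim_config(seed = seed, viruses_per_region = 3, genome_length = 12000,
             n_core_genes = 6, n_variable_pool = 12,
             variable_genes_per_virus = 5,
             core_gene_codons = c(70, 120), variable_gene_codons = c(60, 100),
             hosts_per_region = 2, spacers_per_host = 6,
             host_genome_length = 4500, ...)
}
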