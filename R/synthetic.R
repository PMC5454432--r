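# Seeded generator for synthetic SIRV-like virus populations and host
# CRISPR arrays, with a ground-truth ledger (gene families, spacer sources,
# regional tree, protection) so every downstream stage is testable without
# downloads.

#' Simulation configuration
#'
#' Defaults emulate the SIRV population structure: ~35 kb genomes at ~26.5%
#' G+C carrying a syntenic central block of 30 core genes flanked by
#' terminal variable genes drawn from a pool of 64, two geographic regions,
#' and host CRISPR arrays whose spacers derive mostly from same-region
#' viruses with location-dependent divergence.
#'
#' @param seed integer RNG seed
#' @param n_regions number of geographic regions
#' @param viruses_per_region virus isolates per region
#' @param genome_length virus genome length (bp)
#' @param gc_content target G+C fraction
#' @param n_core_genes core gene families (present everywhere)
#' @param n_variable_pool size of the variable gene-family pool
#' @param variable_genes_per_virus variable families sampled per regional
#'   founder
#' @param core_gene_codons,variable_gene_codons inclusive ranges of internal
#'   codons per gene
#' @param core_substitution_rate,variable_substitution_rate expected
#'   substitutions/site from the root to a tip along the regional tree
#' @param omega_core,omega_variable acceptance probability of nonsynonymous
#'   changes (< 1 gives purifying selection)
#' @param gene_gain_loss_rate gain/loss events per variable gene per tip
#'   branch
#' @param hosts_per_region,spacers_per_host host genomes and spacers per
#'   host array
#' @param spacer_length spacer length (nt)
#' @param local_spacer_fraction fraction of non-decoy spacers drawn from
#'   same-region viruses
#' @param spacer_divergence_local,spacer_divergence_foreign per-base
#'   mutation probability applied to sampled protospacers
#' @param decoy_fraction fraction of spacers that are random sequence
#'   sharing no 12-mer with any virus
#' @param pam_motif IUPAC PAM motif read 5' of the protospacer on the
#'   protospacer strand
#' @param repeat_sequence fixed CRISPR repeat
#' @param host_genome_length host contig length (bp)
#' @param n_anticrispr_pairs protected host x virus pairs flipped to
#'   clearing in the observed infection matrix (planted anti-CRISPR)
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_regions = 2L,
                       viruses_per_region = 5L,
                       genome_length = 35000L,
                       gc_content = 0.265,
                       n_core_genes = 30L,
                       n_variable_pool = 64L,
                       variable_genes_per_virus = 24L,
                       core_gene_codons = c(150L, 250L),
                       variable_gene_codons = c(100L, 220L),
                       core_substitution_rate = 0.05,
                       variable_substitution_rate = 0.08,
                       omega_core = 0.2,
                       omega_variable = 0.5,
                       gene_gain_loss_rate = 0.15,
                       hosts_per_region = 4L,
                       spacers_per_host = 25L,
                       spacer_length = 39L,
                       local_spacer_fraction = 0.8,
                       spacer_divergence_local = 0.05,
                       spacer_divergence_foreign = 0.25,
                       decoy_fraction = 0.15,
                       pam_motif = "CCN",
                       repeat_sequence = "GATAATCTCTTATAGAATTGAAAG",
                       host_genome_length = 8000L,
                       n_anticrispr_pairs = 0L) {
  cfg <- as.list(environment())
  fracs <- c(gc_content, local_spacer_fraction, spacer_divergence_local,
             spacer_divergence_foreign, decoy_fraction, omega_core,
             omega_variable)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (core_substitution_rate < 0 || variable_substitution_rate < 0 ||
      gene_gain_loss_rate < 0) stop("rates must be >= 0")
  mean_gene <- 3 * mean(core_gene_codons) + 6
  if (n_core_genes * mean_gene >= genome_length)
    stop("core genes cannot fit in genome_length")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d: %d regions x %d viruses, ",
                     "%d bp @ %.1f%% G+C, %d core + pool of %d variable, ",
                     "%d hosts/region x %d spacers\n"),
              x$seed, x$n_regions, x$viruses_per_region, x$genome_length,
              100 * x$gc_content, x$n_core_genes, x$n_variable_pool,
              x$hosts_per_region, x$spacers_per_host))
  invisible(x)
}

base_probs_for <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

random_seq <- function(n, base_probs) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_probs[DNA_BASES]),
        collapse = "")
}

# ATG + n_codons stop-free codons + TAA
random_gene <- function(n_codons, base_probs) {
  body <- character(n_codons)
  k <- 0L
  while (k < n_codons) {
    cod <- random_seq(3L, base_probs)
    if (cod %in% STOP_CODONS) next
    k <- k + 1L
    body[k] <- cod
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# codon-level evolution: a binomial number of substitutions is applied one
# by one; proposals drawn from the background base frequencies; changes
# creating a stop are rejected outright and nonsynonymous changes accepted
# with probability omega. Start and stop codons are immutable.
mutate_gene <- function(cds, t, omega, base_probs) {
  len <- nchar(cds)
  mutable <- len - 6L
  if (mutable <= 0L || t <= 0) return(list(seq = cds, n_sub = 0L))
  target <- rbinom(1L, mutable, min(1, t))
  if (target == 0L) return(list(seq = cds, n_sub = 0L))
  ch <- seq_chars(cds)
  accepted <- 0L
  attempts <- 0L
  max_attempts <- 60L * target + 200L
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    pos <- 3L + sample.int(mutable, 1L)
    cur <- ch[pos]
    alts <- setdiff(DNA_BASES, cur)
    b <- sample(alts, 1L, prob = base_probs[alts])
    cpos <- ((pos - 1L) %/% 3L) * 3L + 1L
    old_codon <- paste(ch[cpos:(cpos + 2L)], collapse = "")
    new_chars <- ch[cpos:(cpos + 2L)]
    new_chars[pos - cpos + 1L] <- b
    new_codon <- paste(new_chars, collapse = "")
    if (new_codon %in% STOP_CODONS) next
    if (!identical(aa_of(old_codon), aa_of(new_codon)) &&
        runif(1) > omega) next
    ch[pos] <- b
    accepted <- accepted + 1L
  }
  list(seq = paste(ch, collapse = ""), n_sub = accepted)
}

# per-base mutation with probability q (uniform among the 3 other bases)
mutate_bases <- function(x, q) {
  if (q <= 0) return(list(seq = x, n_mut = 0L))
  ch <- seq_chars(x)
  hit <- which(runif(length(ch)) < q)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  list(seq = paste(ch, collapse = ""), n_mut = length(hit))
}

# plain-R exhaustive window matcher: counts of matching bases for every
# window of the spacer's length (one strand); used for the generator's
# protection truth and as the independent oracle for the compiled matcher
window_counts_r <- function(spacer, genome) {
  s <- seq_chars(spacer)
  g <- seq_chars(genome)
  L <- length(s)
  G <- length(g)
  if (L > G) return(integer(0))
  W <- G - L + 1L
  counts <- integer(W)
  for (k in seq_len(L)) {
    gk <- g[k:(W + k - 1L)]
    counts <- counts + (gk == s[k] & gk %in% DNA_BASES)
  }
  counts
}

# 0-based starts of protospacer sites whose PAM-side bases match the motif
pam_site_starts <- function(genome_seq, L, motif) {
  ch <- seq_chars(genome_seq)
  G <- length(ch)
  m <- nchar(motif)
  mot <- seq_chars(toupper(motif))
  tab <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
  ok_at <- function(offsets, letters) {
    ok <- rep(TRUE, length(offsets))
    for (k in seq_along(letters)) {
      allowed <- strsplit(tab[[letters[k]]], "")[[1]]
      ok <- ok & ch[offsets + k] %in% allowed
    }
    ok
  }
  # plus strand: PAM occupies [s-m, s) left of the protospacer at [s, s+L)
  s_plus <- m:(G - L)
  plus <- s_plus[ok_at(s_plus - m, mot)]
  # minus strand: PAM is revcomp of [s+L, s+L+m)
  comp <- chartr("ACGT", "TGCA", paste(rev(mot), collapse = ""))
  mot_rc <- seq_chars(comp)
  s_minus <- 1:(G - L - m)
  minus <- s_minus[ok_at(s_minus + L, mot_rc)]
  list(plus = plus, minus = minus)
}

all_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1L), k:n))
}

region_labels <- function(n) {
  lab <- c("Yellowstone", "Iceland", "Kamchatka", "Lassen")
  if (n <= length(lab)) lab[seq_len(n)] else
    c(lab, paste0("Region", seq_len(n - length(lab)) + length(lab)))
}

#' Simulate a virus population with host CRISPR arrays
#'
#' Gene families are created once at the root, evolved down a two-level
#' regional tree (region branch 60%, tip branch 40% of the root-to-tip
#' substitution rate) by codon-level mutation with purifying selection, and
#' packed into genomes with a syntenic central core block and terminal
#' variable genes. Hosts carry one repeat-spacer array whose spacers are
#' mutated copies of protospacers sampled at PAM-compatible sites of local
#' or foreign viruses, plus decoys. The observed infection matrix derives
#' from a match-based protection truth (any spacer with >50% identity and a
#' PAM) computed with the generator's own exhaustive matcher.
#'
#' @param config a [sim_config()]
#' @return object of class `sirv_population`: named lists `viruses` and
#'   `hosts` of [genome_record()], `truth` (genes, spacers, protection,
#'   tree), `infection`, `sample_sheet`, `config`
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bp <- base_probs_for(config$gc_content)
  regions <- region_labels(config$n_regions)

  # ---- gene families at the root ----
  fam <- list()
  for (i in seq_len(config$n_core_genes)) {
    nc <- sample(config$core_gene_codons[1]:config$core_gene_codons[2], 1L)
    fam[[sprintf("core%02d", i)]] <- list(
      seq = random_gene(nc, bp), status = "core",
      strand = sample(c("+", "-"), 1L), zone = "center")
  }
  for (j in seq_len(config$n_variable_pool)) {
    nc <- sample(config$variable_gene_codons[1]:
                   config$variable_gene_codons[2], 1L)
    fam[[sprintf("var%02d", j)]] <- list(
      seq = random_gene(nc, bp), status = "variable",
      strand = sample(c("+", "-"), 1L),
      zone = sample(c("left", "right"), 1L))
  }
  core_ids <- names(fam)[vapply(fam, function(f) f$status == "core",
                                logical(1))]
  var_ids <- setdiff(names(fam), core_ids)
  rate_of <- function(id) if (grepl("^core", id))
    config$core_substitution_rate else config$variable_substitution_rate
  omega_of <- function(id) if (grepl("^core", id))
    config$omega_core else config$omega_variable

  # ---- evolve down the regional tree ----
  viruses <- list()
  truth_genes <- list()
  tip_names <- list()
  tip_branches <- character(0)
  for (r in seq_len(config$n_regions)) {
    reg <- regions[r]
    reg_seqs <- lapply(setNames(names(fam), names(fam)), function(id)
      mutate_gene(fam[[id]]$seq, 0.6 * rate_of(id), omega_of(id), bp)$seq)
    founder_vars <- sort(sample(var_ids,
                                min(config$variable_genes_per_virus,
                                    length(var_ids))))
    # intergenic sequence and gap layout are regional properties: tips of a
    # region share them, so zero-rate simulations give identical genomes
    reservoir <- random_seq(config$genome_length, bp)
    gap_weights <- runif(length(fam) + 1L) + 0.5
    tips <- sprintf("SIRV_%s_%d", substr(reg, 1, 3), 1:config$viruses_per_region)
    tip_names[[reg]] <- tips
    for (v in tips) {
      keep <- founder_vars[runif(length(founder_vars)) >=
                             min(1, config$gene_gain_loss_rate)]
      n_gain <- rpois(1L, config$gene_gain_loss_rate *
                        config$variable_genes_per_virus / 2)
      gainable <- setdiff(var_ids, keep)
      gains <- if (n_gain > 0L && length(gainable))
        sample(gainable, min(n_gain, length(gainable))) else character(0)
      content <- c(core_ids, sort(c(keep, gains)))
      genes <- lapply(setNames(content, content), function(id)
        mutate_gene(reg_seqs[[id]], 0.4 * rate_of(id), omega_of(id), bp)$seq)
      g <- assemble_genome(v, reg, genes, fam, config, reservoir,
                           gap_weights)
      viruses[[v]] <- g$record
      truth_genes[[v]] <- g$truth
      tip_branches <- c(tip_branches,
                        sprintf("%s:%.4f", v,
                                0.4 * config$core_substitution_rate))
    }
  }
  tree <- paste0("(", paste(vapply(regions, function(reg) {
    paste0("(", paste(sprintf("%s:%.4f", tip_names[[reg]],
                              0.4 * config$core_substitution_rate),
                      collapse = ","), "):",
           sprintf("%.4f", 0.6 * config$core_substitution_rate))
  }, character(1)), collapse = ","), ");")
  truth_genes <- do.call(rbind, truth_genes)
  rownames(truth_genes) <- NULL

  # ---- hosts and spacers ----
  virus_kmers <- unique(unlist(lapply(viruses, function(v)
    c(all_kmers(v$sequence, 12L), all_kmers(revcomp(v$sequence), 12L)))))
  pam_sites <- lapply(viruses, function(v)
    pam_site_starts(v$sequence, config$spacer_length, config$pam_motif))
  hosts <- list()
  truth_spacers <- list()
  L <- config$spacer_length
  for (r in seq_len(config$n_regions)) {
    reg <- regions[r]
    local_tips <- tip_names[[reg]]
    foreign_tips <- unlist(tip_names[regions[-r]], use.names = FALSE)
    for (h in seq_len(config$hosts_per_region)) {
      hid <- sprintf("HOST_%s_%d", substr(reg, 1, 3), h)
      sp_rows <- list()
      sp_seqs <- character(config$spacers_per_host)
      for (k in seq_len(config$spacers_per_host)) {
        sid <- sprintf("%s_sp%02d", hid, k)
        if (runif(1) < config$decoy_fraction) {
          repeat {
            cand <- random_seq(L, bp)
            if (!any(all_kmers(cand, 12L) %in% virus_kmers) &&
                !any(all_kmers(revcomp(cand), 12L) %in% virus_kmers)) break
          }
          sp_seqs[k] <- cand
          sp_rows[[k]] <- data.frame(
            spacer_id = sid, host_id = hid, class = "decoy",
            source_virus = "", start = NA_integer_, end = NA_integer_,
            strand = "", n_mut = NA_integer_, stringsAsFactors = FALSE)
          next
        }
        local <- runif(1) < config$local_spacer_fraction ||
          !length(foreign_tips)
        src <- if (local) sample(local_tips, 1L) else
          sample(foreign_tips, 1L)
        q <- if (local) config$spacer_divergence_local else
          config$spacer_divergence_foreign
        sites <- pam_sites[[src]]
        strand <- sample(c("+", "-"), 1L,
                         prob = c(length(sites$plus), length(sites$minus)))
        s0 <- if (strand == "+") sample(sites$plus, 1L) else
          sample(sites$minus, 1L)
        proto <- substr(viruses[[src]]$sequence, s0 + 1L, s0 + L)
        if (strand == "-") proto <- revcomp(proto)
        mut <- mutate_bases(proto, q)
        sp_seqs[k] <- mut$seq
        sp_rows[[k]] <- data.frame(
          spacer_id = sid, host_id = hid,
          class = if (local) "local" else "foreign",
          source_virus = src, start = s0, end = s0 + L, strand = strand,
          n_mut = mut$n_mut, stringsAsFactors = FALSE)
      }
      hosts[[hid]] <- build_host(hid, reg, sp_seqs, config, bp)
      truth_spacers[[hid]] <- do.call(rbind, sp_rows)
    }
  }
  truth_spacers <- do.call(rbind, truth_spacers)
  rownames(truth_spacers) <- NULL

  # ---- protection truth and observed infection ----
  spacer_seq <- setNames(
    unlist(lapply(hosts, function(h) {
      f <- h$features[h$features$kind == "spacer", ]
      substring(h$sequence, f$start + 1L, f$end)
    }), use.names = FALSE),
    truth_spacers$spacer_id)
  protection <- list()
  for (hid in names(hosts)) {
    sp_ids <- truth_spacers$spacer_id[truth_spacers$host_id == hid]
    for (vid in names(viruses)) {
      prot <- FALSE
      for (sid in sp_ids) {
        if (spacer_has_protective_match(spacer_seq[[sid]],
                                        viruses[[vid]],
                                        config$pam_motif)) {
          prot <- TRUE
          break
        }
      }
      protection[[length(protection) + 1L]] <- data.frame(
        host_id = hid, virus_id = vid, protected = prot,
        anti_crispr = FALSE, stringsAsFactors = FALSE)
    }
  }
  protection <- do.call(rbind, protection)
  if (config$n_anticrispr_pairs > 0L) {
    idx <- which(protection$protected)
    idx <- head(idx, config$n_anticrispr_pairs)
    protection$anti_crispr[idx] <- TRUE
  }
  infection <- do.call(rbind, lapply(seq_len(nrow(protection)), function(i) {
    clear <- if (protection$protected[i] && !protection$anti_crispr[i])
      0L else 3L
    data.frame(host_id = protection$host_id[i],
               virus_id = protection$virus_id[i],
               titer = c("high", "medium", "low"),
               clearing = clear, stringsAsFactors = FALSE)
  }))

  sample_sheet <- rbind(
    data.frame(id = names(viruses), type = "virus",
               location = vapply(viruses, `[[`, character(1), "location"),
               region = vapply(viruses, `[[`, character(1), "location"),
               stringsAsFactors = FALSE),
    data.frame(id = names(hosts), type = "host",
               location = vapply(hosts, `[[`, character(1), "location"),
               region = vapply(hosts, `[[`, character(1), "location"),
               stringsAsFactors = FALSE))
  rownames(sample_sheet) <- NULL

  structure(list(viruses = viruses, hosts = hosts,
                 truth = list(genes = truth_genes, spacers = truth_spacers,
                              protection = protection, tree = tree),
                 infection = infection, sample_sheet = sample_sheet,
                 config = config),
            class = "sirv_population")
}

# does this spacer have a reportable (>50% identity, anchored) window with
# a PAM in this virus? Plain-R path, independent of the compiled matcher.
spacer_has_protective_match <- function(spacer, virus, pam_motif,
                                        threshold = 0.5, min_anchor = 12L) {
  L <- nchar(spacer)
  G <- nchar(virus$sequence)
  sp <- seq_chars(spacer)
  for (strand in c("+", "-")) {
    gseq <- if (strand == "+") virus$sequence else revcomp(virus$sequence)
    counts <- window_counts_r(spacer, gseq)
    for (w in which(counts / L > threshold)) {
      wc <- seq_chars(substr(gseq, w, w + L - 1L))
      eq <- sp == wc & wc %in% DNA_BASES
      r <- rle(eq)
      run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
      if (run < min_anchor) next
      s0 <- if (strand == "+") w - 1L else G - (w - 1L) - L
      pam <- detect_pam(list(start = s0, end = s0 + L, strand = strand),
                        virus, pam_motif)
      if (pam$pam_present) return(TRUE)
    }
  }
  FALSE
}

assemble_genome <- function(vid, region, genes, fam, config, reservoir,
                            gap_weights) {
  ids <- names(genes)
  zone <- vapply(ids, function(id) fam[[id]]$zone, character(1))
  order_ids <- c(sort(ids[zone == "left"]), sort(ids[zone == "center"]),
                 sort(ids[zone == "right"]))
  gene_bp <- sum(nchar(unlist(genes)))
  n_slots <- length(order_ids) + 1L
  budget <- config$genome_length - gene_bp
  if (budget < 2L * n_slots)
    stop("infeasible packing: ", gene_bp, " bp of genes in a ",
         config$genome_length, " bp genome")
  # largest-remainder allocation of the intergenic budget over the slots
  w <- gap_weights[seq_len(n_slots)]
  raw <- w / sum(w) * budget
  gaps <- floor(raw)
  short <- budget - sum(gaps)
  if (short > 0L) {
    bump <- order(raw - gaps, decreasing = TRUE)[seq_len(short)]
    gaps[bump] <- gaps[bump] + 1L
  }
  gap_at <- c(0L, cumsum(gaps))  # slices of the regional reservoir
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_along(order_ids)) {
    gap <- substr(reservoir, gap_at[i] + 1L, gap_at[i + 1L])
    pieces <- c(pieces, gap)
    pos <- pos + gaps[i]
    id <- order_ids[i]
    s <- genes[[id]]
    strand <- fam[[id]]$strand
    placed <- if (strand == "-") revcomp(s) else s
    pieces <- c(pieces, placed)
    feats[[i]] <- data.frame(
      feature_id = sprintf("%s_%s", vid, id), start = pos,
      end = pos + nchar(s), strand = strand, kind = "CDS",
      stringsAsFactors = FALSE)
    pos <- pos + nchar(s)
  }
  pieces <- c(pieces, substr(reservoir, gap_at[n_slots] + 1L,
                             gap_at[n_slots + 1L]))
  features <- do.call(rbind, feats)
  record <- genome_record(vid, paste(pieces, collapse = ""),
                          location = region, features = features)
  truth <- data.frame(genome_id = vid, feature_id = features$feature_id,
                      family_id = order_ids,
                      status = vapply(order_ids, function(id)
                        fam[[id]]$status, character(1)),
                      start = features$start, end = features$end,
                      strand = features$strand, stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(record = record, truth = truth)
}

build_host <- function(hid, region, spacer_seqs, config, bp) {
  rep_seq <- toupper(config$repeat_sequence)
  rl <- nchar(rep_seq)
  n_sp <- length(spacer_seqs)
  array_seq <- paste0(rep_seq,
                      paste(vapply(spacer_seqs, function(s)
                        paste0(s, rep_seq), character(1)), collapse = ""))
  array_len <- nchar(array_seq)
  flank <- config$host_genome_length - array_len
  if (flank < 2000L) stop("host genome too short for the array")
  pre <- sample(1000:(flank - 1000L), 1L)
  seqs <- paste0(random_seq(pre, bp), array_seq,
                 random_seq(flank - pre, bp))
  feats <- list()
  pos <- pre
  for (k in seq_len(n_sp + 1L)) {
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = sprintf("%s_rep%02d", hid, k), start = pos,
      end = pos + rl, strand = "+", kind = "repeat",
      stringsAsFactors = FALSE)
    pos <- pos + rl
    if (k <= n_sp) {
      sl <- nchar(spacer_seqs[k])
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = sprintf("%s_sp%02d", hid, k), start = pos,
        end = pos + sl, strand = "+", kind = "spacer",
        stringsAsFactors = FALSE)
      pos <- pos + sl
    }
  }
  genome_record(hid, seqs, location = region,
                features = do.call(rbind, feats))
}

#' @export
print.sirv_population <- function(x, ...) {
  cat(sprintf(paste0("<sirv_population> %d viruses, %d hosts, %d spacers ",
                     "(%d decoys), seed %d\n"),
              length(x$viruses), length(x$hosts), nrow(x$truth$spacers),
              sum(x$truth$spacers$class == "decoy"), x$config$seed))
  invisible(x)
}

#' Write a simulated population as a loadable fixture
#'
#' Emits viruses.fasta, hosts.fasta, features.gff, samples.tsv,
#' infection.tsv, the truth tables, tree.nwk and config.json, all loadable
#' by the package's readers unchanged. Identical populations produce
#' byte-identical fixtures.
#'
#' @param pop a [simulate_population()] result
#' @param out_dir output directory (created if needed)
#' @return file paths, invisibly
#' @export
emit_fixture <- function(pop, out_dir) {
  stopifnot(inherits(pop, "sirv_population"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)
  write_fasta(pop$viruses, p("viruses.fasta"))
  write_fasta(pop$hosts, p("hosts.fasta"))
  write_gff(c(pop$viruses, pop$hosts), p("features.gff"))
  wt <- function(df, f)
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(pop$sample_sheet, "samples.tsv")
  wt(pop$infection, "infection.tsv")
  wt(pop$truth$genes, "truth_genes.tsv")
  wt(pop$truth$spacers, "truth_spacers.tsv")
  wt(pop$truth$protection, "truth_protection.tsv")
  writeLines(pop$truth$tree, p("tree.nwk"))
  cfg <- unclass(pop$config)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list.files(out_dir, full.names = TRUE))
}
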