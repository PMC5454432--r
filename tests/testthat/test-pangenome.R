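params <- alignment_params()

test_that("ORF extraction translates both strands and flags bad CDS", {
  feats <- data.frame(feature_id = c("f1", "f2"),
                      start = c(0L, 6L), end = c(6L, 12L),
                      strand = c("+", "-"), kind = "CDS")
  # plus strand ATGTAA -> "M"; minus strand TTACAT revcomps to ATGTAA
  g <- genome_record("g", paste0("ATGTAA", "TTACAT"), features = feats)
  orfs <- extract_orfs(g)
  expect_equal(orfs$protein, c("M", "M"))
  expect_equal(orfs$strand, c("+", "-"))

  feats_bad <- data.frame(feature_id = "odd", start = 0L, end = 4L,
                          strand = "+", kind = "CDS")
  g2 <- genome_record("g2", "ATGTAACC", features = feats_bad)
  expect_error(extract_orfs(g2), "odd")

  # internal stop: excluded but reported
  feats3 <- data.frame(feature_id = "f3", start = 0L, end = 9L,
                       strand = "+", kind = "CDS")
  g3 <- genome_record("g3", "ATGTAAAAA", features = feats3)
  o3 <- extract_orfs(g3)
  expect_equal(nrow(o3), 0)
  expect_equal(attr(o3, "excluded")$orf_id, "f3")
})

test_that("Smith-Waterman equals the brute-force DP oracle", {
  expect_equal(local_align("HEAGAWGHEE", "HEAGAWGHEE", params),
               sum(diag(params$S[strsplit("HEAGAWGHEE", "")[[1]],
                                 strsplit("HEAGAWGHEE", "")[[1]]])))
  expect_equal(local_align("HEAGAWGHEE", "PAWHEAE", params),
               sw_oracle("HEAGAWGHEE", "PAWHEAE", params$S))
  set.seed(42)
  for (i in 1:200) {
    a <- random_protein(sample(3:12, 1))
    b <- random_protein(sample(3:12, 1))
    expect_equal(local_align(a, b, params), sw_oracle(a, b, params$S))
  }
  # no positively scoring pair -> SW floor of zero
  expect_equal(local_align("AAAA", "WWWW", params), 0)
  # symmetry
  expect_equal(local_align("MKVL", "MKIL", params),
               local_align("MKIL", "MKVL", params))
})

test_that("bit scores follow the Karlin-Altschul form and increase in raw", {
  expect_equal(bit_score(0, params), -log(0.041) / log(2))
  expect_equal(bit_score(100, params), (0.267 * 100 - log(0.041)) / log(2))
  raws <- seq(0, 500, by = 7)
  expect_true(all(diff(bit_score(raws, params)) > 0))
})

test_that("the bit-score-ratio screen keeps edges at the threshold", {
  orfs <- data.frame(orf_id = c("x", "y"), genome_id = c("g1", "g2"),
                     start = 0L, end = 0L, strand = "+", cds = "",
                     protein = c("MKVLAAGHEW", "MKVLAAGHEW"))
  e <- build_similarity_graph(orfs, params, 0.3)
  expect_equal(e$ratio, 1.0)  # duplicate proteins

  orfs2 <- data.frame(orf_id = c("x", "y"), genome_id = c("g1", "g2"),
                      start = 0L, end = 0L, strand = "+", cds = "",
                      protein = c("MKVLAAGHEWRRQS", "MKVLCNPDTT"))
  rho <- build_similarity_graph(orfs2, params, 0)$ratio
  expect_true(rho > 0 && rho < 1)
  expect_equal(nrow(build_similarity_graph(orfs2, params, rho)), 1)
  expect_equal(nrow(build_similarity_graph(orfs2, params, rho + 1e-9)), 0)
})

test_that("Markov clustering matches the independent matrix oracle", {
  tri <- function(ids) data.frame(
    orf_a = ids[c(1, 2, 3)], orf_b = ids[c(2, 3, 1)], ratio = 1)
  edges <- rbind(tri(c("a", "b", "c")), tri(c("d", "e", "f")))
  cl <- mcl_cluster(edges, letters[1:6])
  expect_equal(canon_clusters(cl),
               canon_clusters(list(c("a", "b", "c"), c("d", "e", "f"))))

  path <- data.frame(orf_a = c("a", "b", "c"), orf_b = c("b", "c", "d"),
                     ratio = c(1, 0.05, 1))
  cl2 <- mcl_cluster(path, letters[1:4])
  expect_equal(canon_clusters(cl2),
               canon_clusters(list(c("a", "b"), c("c", "d"))))
  expect_equal(canon_clusters(cl2),
               canon_clusters(mcl_oracle(path, letters[1:4])))

  expect_equal(mcl_cluster(path[0, ], "solo"), list("solo"),
               ignore_attr = TRUE)

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    nodes <- paste0("n", 1:n)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.5
    if (!any(keep)) next
    edges <- data.frame(orf_a = nodes[pairs[keep, 1]],
                        orf_b = nodes[pairs[keep, 2]],
                        ratio = round(runif(sum(keep), 0.3, 1), 2))
    expect_equal(canon_clusters(mcl_cluster(edges, nodes)),
                 canon_clusters(mcl_oracle(edges, nodes)))
  }
})

make_two_gene_genomes <- function() {
  set.seed(303)
  cds_a <- paste0("ATG", random_cds(40), "TAA")
  cds_b <- paste0("ATG", random_cds(50), "TAA")
  mk <- function(id, with_b_annotation) {
    seqs <- paste0(random_dna(60, 0.3), cds_a, random_dna(40, 0.3), cds_b,
                   random_dna(60, 0.3))
    feats <- data.frame(feature_id = paste0(id, c("_a", "_b")),
                        start = c(60L, 60L + nchar(cds_a) + 40L),
                        end = c(60L + nchar(cds_a),
                                60L + nchar(cds_a) + 40L + nchar(cds_b)),
                        strand = "+", kind = "CDS")
    if (!with_b_annotation) feats <- feats[1, ]
    genome_record(id, seqs, features = feats)
  }
  list(g1 = mk("g1", TRUE), g2 = mk("g2", TRUE), g3 = mk("g3", FALSE))
}

test_that("six-frame rescue upgrades unannotated exact copies", {
  genomes <- make_two_gene_genomes()
  pg <- pangenome(genomes, params, rescue = TRUE)
  # g3 carries gene b verbatim but unannotated: rescued with a start codon
  bcl <- pg$membership$cluster_id[pg$membership$orf_id == "g1_b"]
  expect_equal(unname(pg$pa_pre_rescue[bcl, "g3"]), "absent")
  expect_equal(unname(pg$pa[bcl, "g3"]), "present")
  expect_equal(unname(pg$status[bcl]), "core")
  # annotated members unchanged
  expect_equal(unname(pg$pa[bcl, "g1"]), "present")
  # six-frame oracle: the protein really is in a translated frame of g3
  prot <- pg$orfs$protein[pg$orfs$orf_id == "g1_b"]
  frames <- sirvpop:::six_frame_segments(genomes$g3)
  expect_true(any(grepl(prot, frames$segment, fixed = TRUE)))
})

test_that("rescue leaves cells absent when the best ratio is below screen", {
  genomes <- make_two_gene_genomes()
  # an impossible screen: nothing rescues
  pa <- rescue_missed_orfs(
    list(c1 = c("g1_b", "g2_b")),
    do.call(rbind, lapply(genomes, extract_orfs)),
    genomes, params, ratio_threshold = 1.5)
  expect_equal(unname(pa["c1", "g3"]), "absent")
})

test_that("core/variable partition follows presence in every genome", {
  genomes <- make_two_gene_genomes()
  pg_norescue <- pangenome(genomes, params, rescue = FALSE)
  bcl <- pg_norescue$membership$cluster_id[
    pg_norescue$membership$orf_id == "g1_b"]
  # present in 2 of 3 genomes only -> variable without rescue
  expect_equal(unname(pg_norescue$status[bcl]), "variable")
  acl <- pg_norescue$membership$cluster_id[
    pg_norescue$membership$orf_id == "g1_a"]
  expect_equal(unname(pg_norescue$status[acl]), "core")
  # core fraction reported per genome
  expect_equal(sort(pg_norescue$core_stats$genome_id), sort(names(genomes)))
  expect_true(all(pg_norescue$core_stats$core_fraction <= 1))
})

test_that("clustering is invariant to genome order and id relabeling", {
  pop <- simulate_population(tiny_sim(seed = 21))
  genomes <- pop$viruses
  pg1 <- pangenome(genomes, params, rescue = FALSE)
  pg2 <- pangenome(rev(genomes), params, rescue = FALSE)
  key <- function(pg) {
    sets <- lapply(pg$clusters, sort)
    sets[order(vapply(sets, `[`, character(1), 1))]
  }
  expect_equal(key(pg1), key(pg2), ignore_attr = TRUE)

  relab <- genomes
  for (n in names(relab)) {
    relab[[n]]$features$feature_id <-
      paste0("zz_", relab[[n]]$features$feature_id)
  }
  pg3 <- pangenome(relab, params, rescue = FALSE)
  strip <- function(k) lapply(k, function(s) sub("^zz_", "", s))
  expect_equal(key(pg1), canon_list <- {
    sets <- strip(key(pg3))
    sets[order(vapply(sets, `[`, character(1), 1))]
  }, ignore_attr = TRUE)
})

test_that("naive ORF caller finds long ORFs on both strands", {
  set.seed(9)
  cds <- paste0("ATG", random_cds(80), "TAA")
  g <- genome_record("g", paste0(random_dna(100, 0.3), cds,
                                 random_dna(100, 0.3)))
  orfs <- naive_orfs(g, min_codons = 60)
  hit <- orfs[orfs$strand == "+" & orfs$start <= 100 &
                orfs$end >= 100 + nchar(cds), ]
  expect_equal(nrow(hit), 1)
  expect_true(substr(hit$cds, 1, 3) %in% c("ATG", "GTG", "TTG"))
  expect_equal(nchar(hit$cds) %% 3, 0)
})
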