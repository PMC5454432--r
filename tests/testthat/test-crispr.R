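test_that("array detection recovers planted repeats at exact coordinates", {
  set.seed(14)
  rep30 <- random_dna(30, 0.3)
  spacers <- replicate(3, random_dna(35, 0.3))
  arr <- paste0(rep30, paste0(spacers, rep30, collapse = ""))
  pre <- random_dna(500, 0.3)
  g <- genome_record("h", paste0(pre, arr, random_dna(400, 0.3)))
  found <- detect_arrays(g)
  expect_length(found, 1)
  a <- found[[1]]
  expect_equal(nrow(a$repeats), 4)
  expect_equal(nrow(a$spacers), 3)
  expect_equal(a$spacers$sequence, spacers)
  expect_equal(a$spacers$start, 500 + 30 + c(0, 65, 130))
  expect_equal(a$consensus, rep30)
  expect_equal(a$start, 500)
  expect_equal(a$end, 500 + nchar(arr))
})

test_that("array detection reports nothing without enough repeats", {
  set.seed(15)
  g <- genome_record("r", random_dna(10000, 0.3))
  expect_length(detect_arrays(g), 0)

  rep30 <- random_dna(30, 0.3)
  two <- paste0(random_dna(300, 0.3), rep30, random_dna(35, 0.3), rep30,
                random_dna(300, 0.3))
  expect_length(detect_arrays(genome_record("t", two), min_repeats = 3), 0)
})

test_that("spacers orient by the flanking repeat", {
  set.seed(16)
  ref <- random_dna(30, 0.3)
  arr <- list(array_id = "a1", host_id = "h", consensus = ref,
              spacers = data.frame(spacer_id = c("s1", "s2"), index = 1:2,
                                   start = c(0L, 65L), end = c(35L, 100L),
                                   sequence = c("ACGTA", "GGTTT")))
  fw <- orient_spacers(arr, ref)
  expect_equal(fw$orientation, rep("forward", 2))
  expect_equal(fw$sequence, c("ACGTA", "GGTTT"))

  arr_rc <- arr
  arr_rc$consensus <- revcomp(ref)
  rv <- orient_spacers(arr_rc, ref)
  expect_equal(rv$orientation, rep("reverse", 2))
  expect_equal(rv$sequence, revcomp(c("GGTTT", "ACGTA")))
  expect_equal(rv$spacer_id, c("s2", "s1"))

  # equidistant consensus -> ambiguous, both orientations emitted
  arr_amb <- arr
  arr_amb$consensus <- "ACGCGT"  # its own reverse complement
  amb <- orient_spacers(arr_amb, "AAAAAA")
  expect_equal(nrow(amb), 4)
  expect_setequal(unique(amb$orientation),
                  c("ambiguous_forward", "ambiguous_reverse"))

  expect_error(orient_spacers(arr, "ACGT"), "incompatible")
})

test_that("a verbatim planted spacer matches at full identity", {
  set.seed(17)
  sp <- random_dna(39, 0.3)
  v <- genome_record("v", paste0(random_dna(300, 0.3), sp,
                                 random_dna(200, 0.3)))
  m <- match_spacer(sp, v)
  plus <- m[m$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$full_identity, 1.0)
  expect_equal(plus$start, 300)
  expect_equal(plus$end, 339)
  expect_equal(plus$half5_identity, 1.0)
  expect_equal(plus$seed_identity, 1.0)

  # planted on the minus strand instead
  v2 <- genome_record("v2", paste0(random_dna(250, 0.3), revcomp(sp),
                                   random_dna(150, 0.3)))
  m2 <- match_spacer(sp, v2)
  minus <- m2[m2$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$full_identity, 1.0)
  expect_equal(minus$start, 250)
})

test_that("the >50% identity threshold is strict", {
  set.seed(18)
  sp <- random_dna(40, 0.5)
  mism <- function(x, k) {
    ch <- strsplit(x, "")[[1]]
    idx <- (length(ch) - k + 1):length(ch)  # damage the tail, keep anchor
    for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  win22 <- mism(sp, 18)   # 22 of 40 identities = 0.55
  win20 <- mism(sp, 20)   # exactly 0.50
  v <- genome_record("v", paste0(random_dna(120, 0.5), win22,
                                 random_dna(90, 0.5), win20,
                                 random_dna(120, 0.5)))
  m <- match_spacer(sp, v)
  expect_true(any(m$start == 120 & abs(m$full_identity - 0.55) < 1e-9))
  expect_false(any(m$start == 120 + 40 + 90))
})

test_that("the matcher agrees with the exhaustive sliding-window oracle", {
  set.seed(19)
  vseq <- random_dna(2000, 0.3)
  v <- genome_record("v", vseq)
  # 30 random spacers, unanchored matching compared window by window
  for (i in 1:30) {
    sp <- random_dna(sample(25:45, 1), 0.3)
    got <- match_spacer(sp, v, min_anchor = 0)
    want <- window_oracle(sp, vseq, min_anchor = 0)
    # the oracle lists all qualifying windows; ours collapses overlaps to
    # local maxima, so every reported window must be in the oracle set with
    # identical identity, and cover every oracle overlap group
    if (nrow(got)) {
      key_o <- paste(want$start, want$strand)
      expect_true(all(paste(got$start, got$strand) %in% key_o))
      mi <- match(paste(got$start, got$strand), key_o)
      expect_equal(got$full_identity, want$full_identity[mi])
    }
    for (st in c("+", "-")) {
      o <- want[want$strand == st, ]
      g <- got[got$strand == st, ]
      if (!nrow(o)) {
        expect_equal(nrow(g), 0)
        next
      }
      # windows on the scanned strand, grouped into overlap chains: one
      # reported window per chain, carrying the chain's maximum identity
      L <- nchar(sp)
      gs <- if (st == "+") o$start else nchar(vseq) - o$start - L
      ord <- order(gs)
      grp <- cumsum(c(1, diff(gs[ord]) >= L))
      expect_equal(nrow(g), max(grp))
      best <- tapply(o$full_identity[ord], grp, max)
      expect_setequal(round(g$full_identity, 9),
                      round(as.numeric(best), 9))
    }
  }
  # planted mutated copies under the default anchored criterion
  for (i in 1:10) {
    sp <- random_dna(39, 0.3)
    mut <- strsplit(sp, "")[[1]]
    for (k in sample(39, 6)) mut[k] <- setdiff(c("A","C","G","T"), mut[k])[1]
    v2seq <- paste0(random_dna(700, 0.3), paste(mut, collapse = ""),
                    random_dna(500, 0.3))
    got <- match_spacer(sp, genome_record("w", v2seq))
    want <- window_oracle(sp, v2seq, min_anchor = 12)
    expect_equal(nrow(got) > 0, nrow(want) > 0)
    if (nrow(got))
      expect_true(all(paste(got$start, got$strand) %in%
                        paste(want$start, want$strand)))
  }
})

test_that("matching is strand-symmetric under genome reverse complement", {
  set.seed(20)
  sp <- random_dna(39, 0.3)
  mut <- strsplit(sp, "")[[1]]
  for (k in sample(39, 5)) mut[k] <- setdiff(c("A","C","G","T"), mut[k])[1]
  vseq <- paste0(random_dna(400, 0.3), paste(mut, collapse = ""),
                 random_dna(300, 0.3))
  m_fwd <- match_spacer(sp, genome_record("v", vseq))
  m_rev <- match_spacer(sp, genome_record("v", revcomp(vseq)))
  G <- nchar(vseq)
  expect_equal(nrow(m_fwd), nrow(m_rev))
  flip <- data.frame(start = G - m_rev$end,
                     strand = ifelse(m_rev$strand == "+", "-", "+"),
                     full_identity = m_rev$full_identity)
  expect_setequal(paste(m_fwd$start, m_fwd$strand, m_fwd$full_identity),
                  paste(flip$start, flip$strand, flip$full_identity))
})

test_that("PAM detection reads the configured side of either strand", {
  # plus strand: CCA immediately 5' of the protospacer
  v <- genome_record("v", paste0("TTTTCCA", "GGGGGGGGGG", "TTTT"))
  match_plus <- list(start = 7L, end = 17L, strand = "+")
  pam <- detect_pam(match_plus, v, "CCN")
  expect_true(pam$pam_present)
  expect_equal(pam$pam_sequence, "CCA")

  v2 <- genome_record("v2", paste0("TTTTTTG", "GGGGGGGGGG", "TTTT"))
  expect_false(detect_pam(list(start = 7L, end = 17L, strand = "+"),
                          v2, "CCN")$pam_present)

  # minus strand: protospacer strand 5' side lies genomically right;
  # genome carries TGG so the protospacer strand reads CCA
  v3 <- genome_record("v3", paste0("AAAA", "GGGGGGGGGG", "TGGAAAA"))
  match_minus <- list(start = 4L, end = 14L, strand = "-")
  pam3 <- detect_pam(match_minus, v3, "CCN")
  expect_true(pam3$pam_present)
  expect_equal(pam3$pam_sequence, "CCA")

  # out of bounds -> absent with empty observed sequence
  v4 <- genome_record("v4", "GGGGGGGGGG")
  pam4 <- detect_pam(list(start = 0L, end = 10L, strand = "+"), v4, "CCN")
  expect_false(pam4$pam_present)
  expect_equal(pam4$pam_sequence, "")
})

fake_matches <- function(host, virus, identity, pam) {
  data.frame(spacer_id = paste0(host, "_sp1"), host_id = host,
             virus_id = virus, start = 100L, end = 139L, strand = "+",
             full_identity = identity, half5_identity = identity,
             seed_identity = identity, pam_present = pam,
             pam_sequence = ifelse(pam, "CCA", "TTG"))
}

fake_infection <- function(host, virus, clearing) {
  x <- data.frame(host_id = host, virus_id = virus,
                  titer = c("high", "medium", "low"), clearing = clearing)
  x$titer <- factor(x$titer, levels = c("high", "medium", "low"))
  x
}

test_that("immunity calls reconcile predictions with observations", {
  # qualifying match with PAM, never cleared: immune, concordant
  calls <- call_immunity(fake_matches("h1", "v1", 1.0, TRUE), "h1", "v1",
                         fake_infection("h1", "v1", c(0, 0, 0)))
  expect_equal(calls$predicted, "immune")
  expect_equal(calls$discordance, "concordant")
  expect_equal(calls$n_matches_with_pam, 1)

  # no matches, cleared at all titers: susceptible, concordant
  calls2 <- call_immunity(fake_matches("x", "y", 1, TRUE)[0, ], "h1", "v1",
                          fake_infection("h1", "v1", c(3, 3, 3)))
  expect_equal(calls2$predicted, "susceptible")
  expect_equal(calls2$discordance, "concordant")

  # qualifying match but clearing at the low titer: anti-CRISPR candidate
  calls3 <- call_immunity(fake_matches("h1", "v1", 0.9, TRUE), "h1", "v1",
                          fake_infection("h1", "v1", c(3, 2, 1)))
  expect_equal(calls3$discordance, "anti_crispr_candidate")

  # predicted susceptible but no clearing at high titer: resistance
  calls4 <- call_immunity(fake_matches("h1", "v1", 0.9, FALSE), "h1", "v1",
                          fake_infection("h1", "v1", c(0, 0, 0)),
                          require_pam = TRUE)
  expect_equal(calls4$predicted, "susceptible")
  expect_equal(calls4$discordance, "resistance_candidate")
  expect_equal(calls4$n_matches_no_pam, 1)

  # matches below the strict threshold never qualify
  calls5 <- call_immunity(fake_matches("h1", "v1", 0.5, TRUE), "h1", "v1")
  expect_equal(calls5$predicted, "susceptible")
  expect_false("discordance" %in% names(calls5))
})
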