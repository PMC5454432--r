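mk_spacers <- function(n, host) {
  data.frame(spacer_id = sprintf("%s_sp%04d", host, seq_len(n)),
             host_id = host, sequence = "", stringsAsFactors = FALSE)
}

mk_match <- function(spacer_ids, virus = "v1", identity = 0.8,
                     start = 100L) {
  if (!length(spacer_ids))
    return(data.frame(spacer_id = character(), host_id = character(),
                      virus_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      full_identity = numeric(), pam_present = logical()))
  data.frame(spacer_id = spacer_ids, host_id = sub("_sp.*", "", spacer_ids),
             virus_id = virus, start = start, end = start + 39L,
             strand = "+", full_identity = identity, pam_present = TRUE,
             stringsAsFactors = FALSE)
}

test_that("match fractions reproduce printed-style percentages", {
  ss <- data.frame(id = c("hY", "hK"), location = c("Yellowstone", "Kamchatka"),
                   region = c("Yellowstone", "Kamchatka"))
  spacers <- rbind(mk_spacers(765, "hY"), mk_spacers(2330, "hK"))
  matches <- rbind(mk_match(spacers$spacer_id[1:225]),
                   mk_match(spacers$spacer_id[766:820]))
  fr <- match_fractions(spacers, matches, ss)$by_location
  expect_equal(fr$pct[fr$location == "Yellowstone"], 29.4)  # 225/765
  expect_equal(fr$n_spacers_matching[fr$location == "Yellowstone"], 225)
  expect_equal(fr$pct[fr$location == "Kamchatka"], 2.4)     # 55/2330
  expect_equal(fr$fraction[fr$location == "Kamchatka"], 55 / 2330)
})

test_that("match fractions handle zero matches and unknown hosts", {
  ss <- data.frame(id = "h1", location = "Lassen", region = "Lassen")
  spacers <- mk_spacers(10, "h1")
  fr <- match_fractions(spacers, mk_match(character(0)), ss)$by_location
  expect_equal(fr$pct, 0)
  expect_equal(fr$n_spacers_matching, 0)

  spacers_bad <- mk_spacers(2, "ghost")
  expect_error(match_fractions(spacers_bad, mk_match(character(0)), ss),
               "ghost")
})

test_that("fractions are invariant to duplicated match rows", {
  ss <- data.frame(id = "h1", location = "Lassen", region = "Lassen")
  spacers <- mk_spacers(8, "h1")
  m <- mk_match(spacers$spacer_id[1:3])
  fr1 <- match_fractions(spacers, m, ss)$by_location
  fr2 <- match_fractions(spacers, rbind(m, m, m), ss)$by_location
  expect_equal(fr1, fr2)
})

test_that("half-up rounding matches the reporting convention", {
  expect_equal(sirvpop:::round_half_up(29.411), 29.4)
  expect_equal(sirvpop:::round_half_up(2.35), 2.4)   # half rounds up
  expect_equal(sirvpop:::round_half_up(2.34999), 2.3)
})

test_that("identity histograms bin reported matches only", {
  ss <- data.frame(id = "h1", location = "Lassen", region = "Lassen")
  m <- mk_match(sprintf("h1_sp%04d", 1:5), identity = 1.0)
  h <- identity_distribution(m, ss)
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_hi, 100)
  expect_equal(h$n_matches, 5)

  h0 <- identity_distribution(mk_match(character(0)), ss)
  expect_equal(nrow(h0), 0)

  # matches at the threshold are excluded (strict)
  m2 <- mk_match("h1_sp0001", identity = 0.5)
  expect_equal(nrow(identity_distribution(m2, ss)), 0)
})

fake_pg <- function() {
  # one genome: core gene [100,400), variable gene [500,800); rest non-coding
  orfs <- data.frame(orf_id = c("o_core", "o_var"), genome_id = "v1",
                     start = c(100L, 500L), end = c(400L, 800L),
                     strand = "+", cds = "", protein = "")
  membership <- data.frame(orf_id = orfs$orf_id, genome_id = "v1",
                           cluster_id = c("c1", "c2"),
                           status = c("core", "variable"))
  list(orfs = orfs, membership = membership)
}

test_that("region partition assigns matches by majority base", {
  g <- list(v1 = genome_record("v1", random_dna(1000, 0.3)))
  pg <- fake_pg()
  inside <- data.frame(spacer_id = "s1", host_id = "h", virus_id = "v1",
                       start = 150L, end = 189L, strand = "+",
                       full_identity = 0.9)
  rp <- region_partition(inside, g, pg)
  expect_equal(rp$n_core, 1)
  expect_equal(rp$n_variable, 0)

  # 39-nt match: 20 bases in the variable gene, 19 intergenic -> variable
  straddle <- data.frame(spacer_id = "s2", host_id = "h", virus_id = "v1",
                         start = 481L, end = 520L, strand = "+",
                         full_identity = 0.9)
  rp2 <- region_partition(straddle, g, pg)
  expect_equal(rp2$n_variable, 1)
  # interval-arithmetic oracle for the same split
  expect_equal(520 - 500, 20)
  expect_equal(500 - 481, 19)

  # flipped split -> non-coding wins
  straddle2 <- straddle
  straddle2$start <- 480L
  straddle2$end <- 519L
  expect_equal(region_partition(straddle2, g, pg)$n_non_coding, 1)

  # counts always tile the total
  both <- rbind(inside, straddle)
  rp3 <- region_partition(both, g, pg)
  expect_equal(rp3$n_core + rp3$n_variable + rp3$n_non_coding,
               rp3$n_matches)
})

test_that("bp coverage uses interval unions and stays in [0, 1]", {
  g <- list(v1 = genome_record("v1", random_dna(1000, 0.3)))
  pg <- fake_pg()
  twice <- data.frame(spacer_id = c("s1", "s2"), host_id = "h",
                      virus_id = "v1", start = c(150L, 150L),
                      end = c(189L, 189L), strand = c("+", "-"),
                      full_identity = 0.9)
  rp <- region_partition(twice, g, pg)
  expect_equal(rp$cov_core, 39 / 300)  # union counted once
  wider <- rbind(twice,
                 data.frame(spacer_id = "s3", host_id = "h",
                            virus_id = "v1", start = 170L, end = 209L,
                            strand = "+", full_identity = 0.9))
  rp2 <- region_partition(wider, g, pg)
  expect_equal(rp2$cov_core, (209 - 150) / 300)
  expect_true(all(unlist(rp2[, c("cov_core", "cov_variable",
                                 "cov_non_coding")]) >= 0))
  expect_true(all(unlist(rp2[, c("cov_core", "cov_variable",
                                 "cov_non_coding")]) <= 1))
  expect_true(rp2$cov_core >= rp$cov_core)  # monotone as matches accrue
})

test_that("region partition demands cluster annotation for the virus", {
  g <- list(v9 = genome_record("v9", random_dna(500, 0.3)))
  m <- data.frame(spacer_id = "s1", host_id = "h", virus_id = "v9",
                  start = 10L, end = 49L, strand = "+", full_identity = 1)
  expect_error(region_partition(m, g, fake_pg()), "cluster annotation")
})
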