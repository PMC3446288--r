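const_track <- function(len, value, chrom = "chrS") {
  structure(stats::setNames(list(rep(value, len)), chrom),
            class = "cons_track")
}

test_that("WIG round-trip preserves scores and missing data stays NA", {
  v <- rep(NA_real_, 500)
  v[101:200] <- round(runif(100), 3)
  v[301:400] <- 0.5
  tr <- structure(list(chrQ = v), class = "cons_track")
  path <- tempfile(fileext = ".wig")
  write_conservation_track(tr, path)
  back <- read_conservation_track(path)
  expect_equal(back$chrQ[101:200], v[101:200], tolerance = 1e-6)
  expect_true(all(is.na(back$chrQ[201:300])))
  # queries beyond the track are missing, never 0
  expect_true(all(is.na(track_values(back, "chrQ", c(600:610)))))
  expect_true(all(is.na(track_values(back, "nope", 1:3))))
})

test_that("a constant track gives a flat skipped-exon profile", {
  set.seed(61)
  anchors <- data.frame(chrom = "chrS", strand = "+",
                        up_start = 1000, up_end = 1100,
                        cas_start = 1300, cas_end = 1400,
                        down_start = 1600, down_end = 1700)
  tr <- const_track(3000, 0.5)
  prof <- profile_ses(list(any = anchors), tr)
  expect_equal(prof$any$n_anchors, 1L)
  expect_equal(length(prof$any$mean_score), 4 * 25 + 2 * 75)
  expect_true(all(prof$any$mean_score == 0.5))
})

test_that("a single anchor's profile equals its raw scores, strand-aware", {
  len <- 3000L
  v <- seq_len(len) / len
  tr <- structure(list(chrS = v), class = "cons_track")
  a_fwd <- data.frame(chrom = "chrS", strand = "+",
                      up_start = 1000, up_end = 1100,
                      cas_start = 1300, cas_end = 1400,
                      down_start = 1600, down_end = 1700)
  p_fwd <- profile_ses(list(s = a_fwd), tr)$s$mean_score
  # manual window: exact positions in transcript orientation
  pos <- c(1075:1099, 1225:1299, 1300:1324, 1375:1399, 1400:1474,
           1600:1624)
  expect_equal(p_fwd, unname(v[pos + 1]))
  # mirrored anchor on the minus strand reads the reverse
  a_rev <- data.frame(chrom = "chrS", strand = "-",
                      up_start = 1600, up_end = 1700,
                      cas_start = 1300, cas_end = 1400,
                      down_start = 1000, down_end = 1100)
  p_rev <- profile_ses(list(s = a_rev), tr)$s$mean_score
  pos_rev <- c(1624:1600, 1474:1400, 1399:1375, 1324:1300, 1299:1225,
               1099:1075)
  expect_equal(p_rev, unname(v[pos_rev + 1]))
})

test_that("short exons contribute their available positions only", {
  tr <- const_track(3000, 0.4)
  a <- data.frame(chrom = "chrS", strand = "+",
                  up_start = 1080, up_end = 1100,   # 20 nt < 25
                  cas_start = 1300, cas_end = 1400,
                  down_start = 1600, down_end = 1700)
  p <- profile_ses(list(s = a), tr)$s$mean_score
  expect_true(all(is.na(p[1:5])))       # missing side of the short exon
  expect_true(all(p[6:25] == 0.4))
})

test_that("planted intronic conservation is recovered in the SES contrast", {
  cfg <- sim_config(event_mix = c(SES = 6),
                    ptc_mix = list(SES = c(ptc_on_inclusion = 0.34,
                                           ptc_on_exclusion = 0.33,
                                           ptc_free = 0.33)),
                    depth = 10L, seed = 62L)
  sim <- simulate_genome_and_models(cfg)
  tr <- simulate_conservation_track(sim, base = 0.3, intron_signal = 0.9,
                                    ptc_signal = 0.3)
  tg <- sim$truth$genes
  mk_anchors <- function(rows) {
    do.call(rbind, lapply(rows, function(i) {
      gid <- tg$gene_id[i]
      g <- sim$models[[gid]]
      uni <- g$exon_union
      cas <- which(uni$start == tg$cassette_start[i])
      data.frame(chrom = g$chrom, strand = g$strand,
                 up_start = uni$start[cas - 1], up_end = uni$end[cas - 1],
                 cas_start = uni$start[cas], cas_end = uni$end[cas],
                 down_start = uni$start[cas + 1],
                 down_end = uni$end[cas + 1])
    }))
  }
  sets <- list(regulated = mk_anchors(which(tg$regulated)),
               unregulated = mk_anchors(which(!tg$regulated)))
  prof <- profile_ses(sets, tr)
  seg <- prof$regulated$segments
  intron <- seg %in% c("up_intron", "down_intron")
  # the +/-10 nt planted PTC windows may clip a base or two of intron
  expect_equal(mean(prof$regulated$mean_score[intron]), 0.9,
               tolerance = 0.01)
  expect_equal(mean(prof$unregulated$mean_score[intron]), 0.3)
  expect_equal(mean(prof$regulated$mean_score[!intron]),
               mean(prof$unregulated$mean_score[!intron]))
  expect_error(profile_ses(list(empty = sets$regulated[0, ]), tr),
               "empty")
})

test_that("PTC profile is baseline-subtracted and zero on a uniform track", {
  set.seed(63)
  anchors <- data.frame(chrom = "chrS", strand = "+",
                        gpos = c(1000, 1450), exon_start = c(900, 1400),
                        exon_end = c(1100, 1600))
  exons <- data.frame(chrom = "chrS", strand = "+",
                      start = seq(200, 1800, by = 200),
                      end = seq(200, 1800, by = 200) + 120)
  tr <- const_track(3000, 0.7)
  p <- profile_ptc(anchors, tr, exons, n_baseline = 5L, seed = 1729L)
  expect_equal(p$n_anchors, 2L)
  expect_true(all(abs(p$mean_score[!is.na(p$mean_score)]) < 1e-12))
  # planted signal around PTCs shows up positive exactly there
  v <- rep(0.4, 3000)
  v[(1000 - 10 + 1):(1000 + 10 + 1)] <- 0.9
  tr2 <- structure(list(chrS = v), class = "cons_track")
  # baseline exons kept clear of the planted window
  base_exons <- data.frame(chrom = "chrS", strand = "+",
                           start = seq(1800, 2600, by = 200),
                           end = seq(1800, 2600, by = 200) + 120)
  p2 <- profile_ptc(anchors[1, ], tr2, base_exons, n_baseline = 5L)
  center <- 101
  expect_true(all(p2$mean_score[(center - 10):(center + 10)] > 0.4))
  expect_true(all(abs(p2$mean_score[c(1:80, 122:201)]) < 1e-12,
                  na.rm = TRUE))
  # baseline sampling is seeded: identical reruns
  p3 <- profile_ptc(anchors, tr, exons, n_baseline = 5L, seed = 1729L)
  expect_identical(p$baseline, p3$baseline)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  m <- matrix(c(8, 2, 1, 9), nrow = 2, byrow = TRUE)
  expect_equal(stats::fisher.test(m)$p.value, oracle_fisher_2x2(m),
               tolerance = 1e-9)
  expect_equal(oracle_fisher_2x2(m), 0.005477, tolerance = 1e-3)
  set.seed(64)
  for (rep in 1:60) {
    r1 <- sample(1:30, 1); r2 <- sample(1:30, 1)
    a <- sample(0:r1, 1); b <- sample(0:r2, 1)
    m <- matrix(c(a, r1 - a, b, r2 - b), nrow = 2, byrow = TRUE)
    if (any(colSums(m) == 0)) next
    expect_equal(stats::fisher.test(m)$p.value, oracle_fisher_2x2(m),
                 tolerance = 1e-7)
  }
})

test_that("stop-codon identity analysis detects the planted UGA bias", {
  cfg <- sim_config(event_mix = c(SES = 8, A5SS = 4, A3SS = 4, MES = 4),
                    ptc_mix = list(SES = c(ptc_on_inclusion = 1),
                                   A5SS = c(ptc_on_inclusion = 1),
                                   A3SS = c(ptc_on_inclusion = 1),
                                   MES = c(ptc_on_exclusion = 1)),
                    ptc_stop_probs = c(TAA = 0.05, TAG = 0.05, TGA = 0.9),
                    depth = 10L, seed = 65L)
  sim <- simulate_genome_and_models(cfg)
  tj <- sim$truth$junctions
  codons <- tj$stop_codon[tj$is_ptc]
  res <- stop_identity_table(codons, sim$models, sim$genome,
                             n_sample = 2e4L, seed = 66L)
  expect_setequal(colnames(res$table), c("UAA", "UAG", "UGA"))
  expect_true(res$proportions["ptc", "UGA"] > 0.6)
  # identical distributions give p ~ 1
  same <- stats::fisher.test(matrix(c(10, 10, 10, 10, 10, 10), nrow = 2,
                                    byrow = TRUE))
  expect_equal(same$p.value, 1)
  # the planted bias is detected against the exonic background
  expect_true("ptc_vs_exonic" %in% names(res$tests))
  expect_lt(res$tests$ptc_vs_exonic$p.value, 0.01)
})

test_that("PTC fraction by expression bins junctions without a read cutoff", {
  r <- ptc_fraction_by_expression(
    is_ptc = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE, NA),
    rpkm_values = c(0.2, 0.5, 0.9, 0.1, 0.4, 0.6, 0.7, 0.8, 1.5, 0.3))
  expect_equal(r$n_ptc[1], 3)
  expect_equal(r$n_nonptc[1], 5)       # the 1.5-RPKM junction is in bin 1
  expect_equal(r$ratio[1], 3 / 5)
  expect_equal(r$ratio[2], 0)
  all_neg <- ptc_fraction_by_expression(rep(FALSE, 5), c(0.5, 1.5, 2.5,
                                                         0.7, 2.1))
  expect_true(all(all_neg$ratio == 0))
  undef <- ptc_fraction_by_expression(c(TRUE, TRUE), c(0.5, 0.6))
  expect_true(is.na(undef$ratio))
})
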