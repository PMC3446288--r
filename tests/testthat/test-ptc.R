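test_that("the 50-nt rule boundary is inclusive: 50 is PTC+, 49 is not", {
  set.seed(41)
  # dist = (90 - 60 - 3) + l4 = 27 + l4
  for (case in list(list(l4 = 23L, dist = 50L, ptc = TRUE),
                    list(l4 = 22L, dist = 49L, ptc = FALSE),
                    list(l4 = 73L, dist = 100L, ptc = TRUE))) {
    bg <- make_boundary_gene(case$l4)
    ref <- longest_isoform(bg$gene, cds_only = TRUE)
    expect_equal(ref$id, "A")
    uni <- bg$gene$exon_union
    j <- list(donor = uni$end[2], acceptor = uni$start[3])
    call <- call_ptc(bg$gene, ref, j, bg$genome)
    expect_equal(call$dist_to_last_junction, case$dist)
    expect_equal(call$is_ptc, case$ptc)
    # oracle agrees at the boundary
    expect_equal(oracle_ptc(bg$gene, ref, j, bg$genome)$is_ptc, case$ptc)
  }
})

test_that("splicing in a canonical junction reproduces the reference", {
  set.seed(42)
  toy <- make_toy_gene(c(200L, 90L, 200L))
  ref <- toy$gene$isoforms[[1]]
  j <- toy_junction(toy$gene, 1L, 2L)
  st <- splice_in_junction(toy$gene, ref, j, toy$genome)
  expect_identical(st$seq, chain_seq(toy$genome, "chrT", "+", ref$exons))
  expect_equal(length(st$junction_offsets), 2L)
  expect_equal(st$cds_start, 9L)
  call <- call_ptc(toy$gene, ref, j, toy$genome)
  expect_false(call$is_ptc)
  expect_match(call$flags, "annotated_stop")
})

test_that("skipping an internal exon shortens the transcript by its length", {
  set.seed(43)
  for (strand in c("+", "-")) {
    toy <- make_toy_gene(c(200L, 90L, 200L), strand = strand)
    ref <- toy$gene$isoforms[[1]]
    j <- toy_junction(toy$gene, 1L, 3L)     # skip exon 2
    st <- splice_in_junction(toy$gene, ref, j, toy$genome)
    expect_equal(nchar(st$seq), isoform_length(ref) - 90L)
    expect_equal(length(st$junction_offsets), 1L)
  }
})

test_that("an A5SS donor inside a reference exon clips that exon", {
  set.seed(44)
  toy <- make_toy_gene(c(200L, 120L, 200L))
  ref <- toy$gene$isoforms[[1]]
  uni <- toy$gene$exon_union
  j <- list(donor = uni$end[2] - 30L, acceptor = uni$start[3])
  st <- splice_in_junction(toy$gene, ref, j, toy$genome)
  expect_equal(nchar(st$seq), isoform_length(ref) - 30L)
  expect_equal(st$exon_chain$end[2], uni$end[2] - 30L)
  # downstream chain unchanged
  expect_equal(st$exon_chain$start[3], uni$start[3])
  # independent sequence check: manual splice of the clipped chain
  chrom <- as.character(toy$genome[[1]])
  manual <- paste0(substr(chrom, uni$start[1] + 1L, uni$end[1]),
                   substr(chrom, uni$start[2] + 1L, uni$end[2] - 30L),
                   substr(chrom, uni$start[3] + 1L, uni$end[3]))
  expect_identical(st$seq, manual)
})

test_that("junctions outside the reference isoform raise errors", {
  set.seed(45)
  toy <- make_toy_gene(c(200L, 90L, 200L))
  ref <- toy$gene$isoforms[[1]]
  span <- gene_span(toy$gene)
  expect_error(splice_in_junction(toy$gene, ref,
                                  list(donor = span[2] + 50L,
                                       acceptor = span[2] + 150L),
                                  toy$genome),
               "outside reference")
})

test_that("find_first_stop scans in-frame triplets only", {
  expect_equal(find_first_stop("ATGAAATGACCC", 0L),
               list(stop_pos = 6L, stop_codon = "TGA"))
  # the TGA at offset 5 is out of frame and must be ignored
  expect_equal(find_first_stop("ATGAATGAATAA", 0L),
               list(stop_pos = 9L, stop_codon = "TAA"))
  expect_true(is.na(find_first_stop("ATGAAACCCGGG", 0L)$stop_pos))
  expect_true(is.na(find_first_stop("AT", 0L)$stop_pos))
  # frame shift changes which stop is seen
  expect_equal(find_first_stop(paste0("C", "ATGAATGAATAA"), 1L)$stop_pos,
               10L)
})

test_that("call_ptc equals brute-force full-isoform translation on all junctions", {
  cfg <- sim_config(event_mix = c(SES = 3, MES = 2, A5SS = 2, A3SS = 2,
                                  MXE = 2, AFE = 1, ALE = 1),
                    depth = 10L, seed = 46L)
  sim <- simulate_genome_and_models(cfg)
  db <- build_combinatorial_db(sim$models, sim$genome)
  checked <- 0L
  for (i in seq_len(nrow(db$junctions))) {
    j <- db$junctions[i, ]
    g <- sim$models[[j$gene_id]]
    ref <- longest_isoform(g, cds_only = TRUE)
    mine <- tryCatch(call_ptc(g, ref, j, sim$genome),
                     error = function(e) NULL)
    theirs <- tryCatch(oracle_ptc(g, ref, j, sim$genome),
                       error = function(e) NULL)
    expect_equal(is.null(mine), is.null(theirs), info = j$junction_id)
    if (!is.null(mine) && !is.null(theirs)) {
      checked <- checked + 1L
      expect_equal(mine$is_ptc, theirs$is_ptc, info = j$junction_id)
      if (isTRUE(mine$is_ptc))
        expect_equal(mine$stop_codon, theirs$stop_codon,
                     info = j$junction_id)
    }
  }
  expect_gt(checked, 100L)
})

test_that("raising ptc_min_dist never converts PTC- to PTC+", {
  cfg <- sim_config(event_mix = c(SES = 2, A3SS = 1), depth = 10L,
                    seed = 47L)
  sim <- simulate_genome_and_models(cfg)
  db <- build_combinatorial_db(sim$models, sim$genome)
  t50 <- ptc_table(db, sim$genome, ptc_min_dist = 50L)
  t80 <- ptc_table(db, sim$genome, ptc_min_dist = 80L)
  strict <- !is.na(t80$is_ptc) & t80$is_ptc
  loose <- !is.na(t50$is_ptc) & t50$is_ptc
  expect_true(all(loose[strict]))
})

test_that("canonical junctions of CDS-bearing references are never PTC+", {
  cfg <- sim_config(event_mix = c(SES = 2, MES = 1, A5SS = 1, MXE = 1,
                                  ALE = 1), depth = 10L, seed = 48L)
  sim <- simulate_genome_and_models(cfg)
  for (gid in names(sim$models)) {
    g <- sim$models[[gid]]
    ref <- longest_isoform(g, cds_only = TRUE)
    ex <- ref$exons
    for (i in seq_len(nrow(ex) - 1L)) {
      j <- if (g$strand == "+")
        list(donor = ex$end[i], acceptor = ex$start[i + 1L])
      else list(donor = ex$start[i], acceptor = ex$end[i + 1L])
      expect_false(call_ptc(g, ref, j, sim$genome)$is_ptc)
    }
  }
})

test_that("in-frame stop-free skips never create a PTC (MES identity)", {
  cfg <- sim_config(event_mix = c(MES = 3, SES = 2),
                    ptc_mix = list(MES = c(ptc_free = 1),
                                   SES = c(ptc_free = 1)),
                    depth = 10L, seed = 49L)
  sim <- simulate_genome_and_models(cfg)
  tj <- sim$truth$junctions
  skips <- tj[tj$role == "alt_unique", ]
  expect_gt(nrow(skips), 0L)
  for (i in seq_len(nrow(skips))) {
    g <- sim$models[[skips$gene_id[i]]]
    ref <- longest_isoform(g, cds_only = TRUE)
    f <- strsplit(skips$junction_id[i], "|", fixed = TRUE)[[1]]
    j <- list(donor = as.integer(f[4]), acceptor = as.integer(f[5]))
    expect_false(call_ptc(g, ref, j, sim$genome)$is_ptc)
    expect_false(oracle_ptc(g, ref, j, sim$genome)$is_ptc)
  }
})

test_that("inclusion/exclusion PTC semantics label events correctly", {
  calls <- data.frame(junction_id = c("i1", "i2", "x1", "c1"),
                      is_ptc = c(TRUE, FALSE, FALSE, NA))
  ev <- function(cls, inc, exc)
    list(event_id = "e", gene_id = "g", cls = cls, inclusion = inc,
         exclusion = exc, affected_exons = 1L)
  expect_equal(classify_inclusion_exclusion(
    ev("SES", c("i1", "i2"), "x1"), calls), "ptc_on_inclusion")
  expect_equal(classify_inclusion_exclusion(
    ev("SES", "x1", "i1"), calls), "ptc_on_exclusion")
  expect_equal(classify_inclusion_exclusion(
    ev("SES", "i2", "x1"), calls), "ptc_free")
  expect_equal(classify_inclusion_exclusion(
    ev("SES", "i1", "i1"), calls), "both_ptc")
  expect_true(is.na(classify_inclusion_exclusion(
    ev("ALE", "i1", "x1"), calls)))
  # all-NA side propagates NA
  expect_true(is.na(classify_inclusion_exclusion(
    ev("SES", "c1", "x1"), calls)))
})
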