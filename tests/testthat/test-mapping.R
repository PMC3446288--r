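test_that("exact junction-window reads, exonic reads and ambiguity resolve per policy", {
  set.seed(21)
  toy <- make_toy_gene(c(200L, 120L, 200L))
  db <- build_combinatorial_db(list(toy = toy$gene), toy$genome,
                               flank_len = 70L)
  j12 <- db$junctions[db$junctions$donor_exon == 1 &
                        db$junctions$acceptor_exon == 2, ]
  # 75-mer centred on the junction boundary
  win <- substring(j12$seq, 70L - 37L + 1L, 70L - 37L + 75L)
  # a read wholly inside exon 1
  chrom <- as.character(toy$genome[[1]])
  uni <- toy$gene$exon_union
  exonic <- substr(chrom, uni$start[1] + 11L, uni$start[1] + 85L)
  # an intronic and an intergenic read
  intronic <- substr(chrom, uni$end[1] + 21L, uni$end[1] + 95L)
  intergenic <- substr(chrom, 11L, 85L)
  reads <- Biostrings::DNAStringSet(c(jr = win, er = exonic,
                                      ir = intronic, gr = intergenic,
                                      short = "ACGACG"))
  res <- map_reads(reads, db, toy$genome)
  expect_equal(res$target,
               c("junction", "genome_exonic", "genome_intronic",
                 "genome_intergenic", "unmapped"))
  expect_equal(res$junction_id[1], j12$junction_id)
  expect_equal(res$truncation_rounds, rep(0L, 5))
  expect_equal(res$gene_id[2], "toy")

  # a read matching two junction windows identically is unmapped:
  # duplicate the gene sequence elsewhere so two junctions share seq
  dup <- make_toy_gene(c(200L, 120L, 200L), gene_id = "dup",
                       chrom = "chrD")
  genome2 <- c(toy$genome, Biostrings::DNAStringSet(
    stats::setNames(as.character(toy$genome[[1]]), "chrD")))
  g2 <- toy$gene
  dupg <- gene_model("dup", "chrD", "+", toy$gene$isoforms)
  db2 <- build_combinatorial_db(list(toy = toy$gene, dup = dupg), genome2)
  res2 <- map_reads(Biostrings::DNAStringSet(c(jr = win)), db2, genome2)
  expect_equal(res2$target, "unmapped")
})

test_that("reverse-strand junction reads map and every read gets one target", {
  set.seed(22)
  toy <- make_toy_gene(c(200L, 120L, 200L), strand = "-")
  db <- build_combinatorial_db(list(toy = toy$gene), toy$genome)
  iso <- toy$gene$isoforms[[1]]
  tx <- chain_seq(toy$genome, "chrT", "-", iso$exons)
  offs <- cumsum(iso$exons$end - iso$exons$start)
  # read spanning the first junction with 40/35 split
  r <- substring(tx, offs[1] - 40L + 1L, offs[1] + 35L)
  res <- map_reads(Biostrings::DNAStringSet(c(a = r)), db, toy$genome)
  expect_equal(res$target, "junction")
  expect_equal(db$junctions$donor_exon[match(res$junction_id,
                                             db$junctions$junction_id)], 1L)
})

test_that("internal mapper equals the brute-force substring oracle", {
  cfg <- sim_config(event_mix = c(SES = 2, A5SS = 1, MXE = 1),
                    depth = 60L, seed = 23L)
  sim <- simulate_genome_and_models(cfg)
  reads <- simulate_reads(sim)$WT$reads
  reads <- reads[seq_len(min(200L, length(reads)))]
  db <- build_combinatorial_db(sim$models, sim$genome)
  res <- map_reads(reads, db, sim$genome)
  expected <- oracle_map(reads, db, sim$genome)
  got <- ifelse(res$target == "junction", res$junction_id,
                ifelse(res$target == "unmapped", "unmapped", "genome"))
  expect_identical(unname(got), unname(expected))
})

test_that("lowering anchor_min never loses junction reads", {
  cfg <- sim_config(event_mix = c(SES = 2, MES = 1), depth = 150L,
                    seed = 24L)
  sim <- simulate_genome_and_models(cfg)
  reads <- simulate_reads(sim)$WT$reads
  db <- build_combinatorial_db(sim$models, sim$genome)
  n_prev <- -1L
  for (a in c(10L, 7L, 5L, 3L)) {
    res <- map_reads(reads, db, sim$genome,
                     mapping_params(anchor_min = a, trunc_min_len = 20L))
    n <- sum(res$target == "junction")
    if (n_prev >= 0L) expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("3' truncation rescues multi-junction reads and records rounds", {
  set.seed(25)
  # short middle exon (60 nt): a 75-mer read can span both junctions
  toy <- make_toy_gene(c(200L, 60L, 200L))
  db <- build_combinatorial_db(list(toy = toy$gene), toy$genome,
                               flank_len = 70L)
  iso <- toy$gene$isoforms[[1]]
  tx <- chain_seq(toy$genome, "chrT", "+", iso$exons)
  offs <- cumsum(iso$exons$end - iso$exons$start)
  # spans exon1/exon2 junction at offset 5 and exon2/exon3 at offset 65:
  # full length matches no single junction window; the first 65 bases
  # fit the exon1-exon2 window
  r <- substring(tx, offs[1] - 5L + 1L, offs[1] - 5L + 75L)
  full <- map_reads(Biostrings::DNAStringSet(c(x = r)), db, toy$genome)
  expect_equal(full$target, "unmapped")
  resc <- truncate_and_rescue(Biostrings::DNAStringSet(c(x = r)), db,
                              toy$genome)
  expect_equal(resc$target, "junction")
  expect_equal(resc$truncation_rounds, 1L)
  expect_equal(db$junctions$donor_exon[match(resc$junction_id,
                                             db$junctions$junction_id)], 1L)
  # a read that never maps exhausts floor((75-25)/10) = 5 rounds
  never <- Biostrings::DNAStringSet(c(n = strrep("ACG", 25L)))
  res_n <- truncate_and_rescue(never, db, toy$genome)
  expect_equal(res_n$target, "unmapped")
  expect_equal(res_n$truncation_rounds, 5L)
})

test_that("SAM import decodes index hits, N-gaps, and skips junk", {
  set.seed(26)
  toy <- make_toy_gene(c(200L, 120L, 200L))
  db <- build_combinatorial_db(list(toy = toy$gene), toy$genome)
  uni <- toy$gene$exon_union
  j12 <- db$junctions[db$junctions$donor_exon == 1 &
                        db$junctions$acceptor_exon == 2, ]
  chrom <- as.character(toy$genome[[1]])
  clen <- nchar(chrom)
  gap <- uni$start[2] - uni$end[1]
  sam <- tempfile(fileext = ".sam")
  seq75 <- strrep("A", 75L)
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:chrT\tLN:%d", clen),
    sprintf("@SQ\tSN:%s\tLN:140", j12$junction_id),
    # junction-index hit
    paste("r1", 0, j12$junction_id, 10, 60, "75M", "*", 0, 0, seq75, "*",
          sep = "\t"),
    # genome hit with an N gap matching the junction intron
    paste("r2", 0, "chrT", uni$end[1] - 40L + 1L, 60,
          sprintf("40M%dN35M", gap), "*", 0, 0, seq75, "*", sep = "\t"),
    # plain exonic genome hit
    paste("r3", 0, "chrT", uni$start[1] + 5L, 60, "75M", "*", 0, 0,
          seq75, "*", sep = "\t"),
    # unmapped record
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, seq75, "*", sep = "\t"),
    # secondary alignment: ignored
    paste("r5", 256, "chrT", uni$start[1] + 5L, 60, "75M", "*", 0, 0,
          "*", "*", sep = "\t")
  ), sam)
  res <- import_sam(sam, db, toy$genome)
  expect_equal(nrow(res), 4L)   # r5 dropped
  expect_equal(res$target[res$read_id == "r1"], "junction")
  expect_equal(res$junction_id[res$read_id == "r1"], j12$junction_id)
  expect_equal(res$target[res$read_id == "r2"], "junction")
  expect_equal(res$junction_id[res$read_id == "r2"], j12$junction_id)
  expect_equal(res$target[res$read_id == "r3"], "genome_exonic")
  expect_equal(res$target[res$read_id == "r4"], "unmapped")
})

test_that("mapping partitions reads: one assignment per input read", {
  cfg <- sim_config(event_mix = c(SES = 1, ALE = 1), depth = 80L,
                    seed = 27L)
  sim <- simulate_genome_and_models(cfg)
  reads <- simulate_reads(sim)$KO$reads
  db <- build_combinatorial_db(sim$models, sim$genome)
  res <- map_reads(reads, db, sim$genome)
  expect_equal(nrow(res), length(reads))
  expect_setequal(res$read_id, names(reads))
  expect_true(all(res$target %in% c("junction", "genome_exonic",
                                    "genome_intronic",
                                    "genome_intergenic", "unmapped")))
})
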