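test_that("a gene with n non-overlapping exons yields n(n-1)/2 junctions", {
  set.seed(7)
  for (n in c(2, 4, 7, 12)) {
    for (strand in c("+", "-")) {
      toy <- make_toy_gene(rep(100L, n), strand = strand)
      db <- build_combinatorial_db(list(toy = toy$gene), toy$genome,
                                   flank_len = 70L)
      expect_equal(nrow(db$junctions), n * (n - 1) / 2)
      # every canonical (consecutive) junction of the isoform is present
      iso <- toy$gene$isoforms[[1]]
      for (i in seq_len(n - 1L)) {
        j <- toy_junction(toy$gene, i, i + 1L)
        expect_true(any(db$junctions$donor == j$donor &
                          db$junctions$acceptor == j$acceptor))
      }
    }
  }
  toy1 <- make_toy_gene(c(400L), stop_in_last = FALSE)
  db1 <- build_combinatorial_db(list(toy = toy1$gene), toy1$genome)
  expect_equal(nrow(db1$junctions), 0L)
})

test_that("overlapping exon variants never junction with each other", {
  # 5 exons where exons 2 and 3 overlap (A5SS-style variants):
  # valid ordered non-overlapping pairs among {1,2,4,5} and {1,3,4,5}
  # minus the 2-3 pair = 9 junctions
  set.seed(8)
  toy <- make_toy_gene(c(150L, 100L, 100L, 120L), intron = 200L)
  uni <- toy$gene$exon_union
  # add a staggered boundary variant of exon 2 (overlaps exon 2,
  # distinct at both boundaries so all 9 junctions are distinct keys)
  iso2 <- isoform("toy_2", data.frame(
    start = c(uni$start[1], uni$start[2] + 10L, uni$start[3], uni$start[4]),
    end = c(uni$end[1], uni$end[2] + 30L, uni$end[3], uni$end[4])))
  g <- gene_model("toy", toy$gene$chrom, "+",
                  c(toy$gene$isoforms, list(toy_2 = iso2)))
  expect_equal(nrow(g$exon_union), 5L)
  db <- build_combinatorial_db(list(toy = g), toy$genome)
  # brute-force oracle: enumerate ordered non-overlapping pairs
  uni5 <- g$exon_union
  cnt <- 0L
  for (u in 1:4) for (v in (u + 1L):5L)
    if (uni5$end[u] <= uni5$start[v] || uni5$end[v] <= uni5$start[u])
      cnt <- cnt + 1L
  expect_equal(cnt, 9L)
  expect_equal(nrow(db$junctions), 9L)
})

test_that("junction sequences equal independent genome extraction", {
  set.seed(9)
  for (strand in c("+", "-")) {
    toy <- make_toy_gene(c(200L, 90L, 120L), strand = strand)
    db <- build_combinatorial_db(list(toy = toy$gene), toy$genome,
                                 flank_len = 70L)
    chrom <- as.character(toy$genome[[1]])
    for (i in seq_len(nrow(db$junctions))) {
      j <- db$junctions[i, ]
      uni <- toy$gene$exon_union
      up <- uni[j$donor_exon, ]; dn <- uni[j$acceptor_exon, ]
      # independent extraction with plain substring + manual revcomp
      revcomp <- function(x) {
        chartr("ACGT", "TGCA",
               paste(rev(strsplit(x, "")[[1]]), collapse = ""))
      }
      if (strand == "+") {
        expected <- paste0(substr(chrom, up$end - 70L + 1L, up$end),
                           substr(chrom, dn$start + 1L, dn$start + 70L))
      } else {
        expected <- paste0(
          revcomp(substr(chrom, up$start + 1L, up$start + 70L)),
          revcomp(substr(chrom, dn$end - 70L + 1L, dn$end)))
      }
      expect_identical(j$seq, expected)
    }
    # flank truncation: exon 2 (90 nt) is shorter than flank 100
    db2 <- build_combinatorial_db(list(toy = toy$gene), toy$genome,
                                  flank_len = 100L)
    short <- db2$junctions[db2$junctions$donor_exon == 2 |
                             db2$junctions$acceptor_exon == 2, ]
    expect_true(all(short$truncated))
    expect_true(all(nchar(short$seq) < 200L))
  }
})

test_that("FASTA export follows the gene|chrom|strand|donor|acceptor grammar", {
  set.seed(10)
  toy <- make_toy_gene(c(150L, 100L, 150L))
  db <- build_combinatorial_db(list(toy = toy$gene), toy$genome)
  fa <- tempfile(fileext = ".fa")
  export_junction_fasta(db, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), nrow(db$junctions))
  expect_true(all(grepl("^[^|]+\\|[^|]+\\|[+-]\\|[0-9]+\\|[0-9]+$",
                        names(seqs))))
  f <- strsplit(names(seqs)[1], "|", fixed = TRUE)[[1]]
  expect_equal(f[1], "toy")
  expect_equal(f[2], "chrT")
  expect_equal(as.integer(f[4]), db$junctions$donor[1])
})

test_that("de novo junction import deduplicates, assigns genes, flags ambiguity", {
  set.seed(11)
  toyA <- make_toy_gene(c(150L, 100L, 150L), gene_id = "gA", chrom = "chrT")
  db <- build_combinatorial_db(list(gA = toyA$gene), toyA$genome)
  n0 <- nrow(db$junctions)
  uni <- toyA$gene$exon_union

  # empty BED: unchanged
  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(import_denovo_junctions(db, empty, toyA$genome)$junctions),
               n0)

  # a junction identical to a combinatorial one: no new record
  dup <- tempfile(fileext = ".bed")
  writeLines(paste("chrT", uni$end[1], uni$start[2], "j1", 1, "+",
                   sep = "\t"), dup)
  expect_equal(nrow(import_denovo_junctions(db, dup, toyA$genome)$junctions),
               n0)

  # novel acceptor inside the gene span: one new denovo record
  nov <- tempfile(fileext = ".bed")
  writeLines(paste("chrT", uni$end[1], uni$start[2] + 10L, "j2", 1, "+",
                   sep = "\t"), nov)
  db2 <- import_denovo_junctions(db, nov, toyA$genome)
  expect_equal(nrow(db2$junctions), n0 + 1L)
  new <- db2$junctions[n0 + 1L, ]
  expect_equal(new$source, "denovo_import")
  expect_equal(new$gene_id, "gA")
  expect_equal(nchar(new$seq), 140L)

  # outside any gene span: assigned to "intergenic"
  faroff <- tempfile(fileext = ".bed")
  writeLines(paste("chrT", 10, 100, "j3", 1, "+", sep = "\t"), faroff)
  db3 <- import_denovo_junctions(db, faroff, toyA$genome)
  expect_equal(db3$junctions$gene_id[n0 + 1L], "intergenic")

  # TopHat-style BED12 whose blocks flank the gap decodes to the
  # same intron as the 6-column form
  th <- tempfile(fileext = ".bed")
  i0 <- uni$end[1]; i1 <- uni$start[2] + 10L
  writeLines(paste("chrT", i0 - 20L, i1 + 20L, "jt", 5, "+", i0 - 20L,
                   i1 + 20L, "0", 2, "20,20,",
                   paste0("0,", i1 + 20L - (i0 - 20L) - 20L, ","),
                   sep = "\t"), th)
  db4 <- import_denovo_junctions(db, th, toyA$genome)
  expect_equal(db4$junctions$donor[n0 + 1L], i0)
  expect_equal(db4$junctions$acceptor[n0 + 1L], i1)
})

test_that("a junction contained in two gene spans is dropped as ambiguous", {
  set.seed(12)
  toy <- make_toy_gene(c(150L, 100L, 150L), gene_id = "gA")
  # a second gene overlapping the first's span on the same strand
  uni <- toy$gene$exon_union
  iso2 <- isoform("gB_1", data.frame(start = uni$start + 5L,
                                     end = uni$end - 5L))
  gB <- gene_model("gB", "chrT", "+", list(gB_1 = iso2))
  db <- build_combinatorial_db(list(gA = toy$gene, gB = gB), toy$genome)
  amb <- tempfile(fileext = ".bed")
  writeLines(paste("chrT", uni$end[1] + 1L, uni$start[2] - 1L, "jx", 1,
                   "+", sep = "\t"), amb)
  db2 <- import_denovo_junctions(db, amb, toy$genome)
  expect_equal(attr(db2, "ambiguous"), 1L)
  expect_equal(nrow(db2$junctions), nrow(db$junctions))
})

test_that("oversized genes trip the max_exons guard and bad exons error", {
  set.seed(13)
  toy <- make_toy_gene(rep(90L, 6))
  expect_error(build_combinatorial_db(list(toy = toy$gene), toy$genome,
                                      max_exons = 5L), "max_exons")
  bad <- toy$gene
  bad$exon_union$end[6] <- length(toy$genome[[1]]) + 100L
  expect_error(build_combinatorial_db(list(toy = bad), toy$genome),
               "chromosome bounds")
})
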