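# Fixtures are built in code: small designed genes with stop-free
# exonic sequence ({A,C,G} alphabet) so stop codons sit exactly where
# a test plants them.

rseq <- function(n, letters = c("A", "C", "G")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

plant_at <- function(seq, pos0, what) {
  substr(seq, pos0 + 1L, pos0 + nchar(what)) <- what
  seq
}

# A toy gene laid out on its own chromosome: exon lengths `lens`,
# constant intron length, optional reverse strand.  The single
# isoform carries all exons with cds_start = 9 (an ATG is planted)
# and, unless stop_in_last = FALSE, a TAA planted in frame 30 nt into
# the last exon.
make_toy_gene <- function(lens, intron = 200L, strand = "+",
                          gene_id = "toy", chrom = "chrT",
                          stop_in_last = TRUE, pad = 300L) {
  n <- length(lens)
  local <- character(0)
  exons <- list()
  cur <- 0L
  for (i in seq_len(n)) {
    exons[[i]] <- c(cur, cur + lens[i])
    local <- c(local, rseq(lens[i]))
    cur <- cur + lens[i]
    if (i < n) {
      local <- c(local, rseq(intron, c("A", "C", "G", "T")))
      cur <- cur + intron
    }
  }
  seq <- paste(local, collapse = "")
  seq <- plant_at(seq, exons[[1]][1] + 9L, "ATGC")
  cds_end <- NA_integer_
  if (stop_in_last) {
    cb <- sum(lens[-n]) - 9L
    p <- (3L - cb %% 3L) %% 3L
    p <- p + 3L * ceiling((30L - p) / 3)
    seq <- plant_at(seq, exons[[n]][1] + p, "TAA")
    cds_end <- sum(lens[-n]) + p + 3L
  }
  L <- nchar(seq)
  gseq <- seq
  if (strand == "-")
    gseq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
  to_g <- function(iv) {
    if (strand == "+") c(pad + iv[1], pad + iv[2])
    else c(pad + L - iv[2], pad + L - iv[1])
  }
  ex_g <- do.call(rbind, lapply(exons, to_g))
  chain <- data.frame(start = as.integer(ex_g[, 1]),
                      end = as.integer(ex_g[, 2]))
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste0(rseq(pad, c("A", "C", "G", "T")), gseq,
           rseq(pad, c("A", "C", "G", "T"))), chrom))
  iso <- isoform(paste0(gene_id, "_1"), chain, cds_start = 9L,
                 cds_end = cds_end)
  g <- gene_model(gene_id, chrom, strand,
                  stats::setNames(list(iso), iso$id), sources = "toy")
  list(gene = g, genome = genome, local_exons = exons, local_seq = seq)
}

# Hand-built poison-exon gene: backbone A skips the cassette e3 and
# carries the CDS; the cassette holds an in-frame stop whose distance
# to the last exon-exon boundary is (l3 - p - 3) + l4, tuned exactly.
make_boundary_gene <- function(l4, p = 60L) {
  lens <- c(150L, 90L, 90L, l4, 150L)
  local <- character(0)
  exons <- list()
  cur <- 0L
  for (i in seq_along(lens)) {
    exons[[i]] <- c(cur, cur + lens[i])
    local <- c(local, rseq(lens[i]))
    cur <- cur + lens[i]
    if (i < length(lens)) {
      local <- c(local, rseq(120L, c("A", "C", "G", "T")))
      cur <- cur + 120L
    }
  }
  seq <- paste(local, collapse = "")
  seq <- plant_at(seq, exons[[1]][1] + 9L, "ATGC")
  seq <- plant_at(seq, exons[[3]][1] + p, "TAA")     # poison stop
  # annotated stop for A (exons 1,2,4,5): in frame 30+ nt into e5
  cbA <- (150L + 90L + l4) - 9L
  pa <- (3L - cbA %% 3L) %% 3L
  pa <- pa + 3L * ceiling((30L - pa) / 3)
  seq <- plant_at(seq, exons[[5]][1] + pa, "TAA")
  genome <- Biostrings::DNAStringSet(stats::setNames(seq, "chrB"))
  ch <- function(ix) data.frame(
    start = vapply(ix, function(i) exons[[i]][1], integer(1)),
    end = vapply(ix, function(i) exons[[i]][2], integer(1)))
  isoA <- isoform("A", ch(c(1, 2, 4, 5)), cds_start = 9L,
                  cds_end = (150L + 90L + l4) + pa + 3L)
  isoB <- isoform("B", ch(1:5))
  g <- gene_model("bg", "chrB", "+", list(A = isoA, B = isoB))
  list(gene = g, genome = genome)
}

# junction between two exon-union rows of a gene, by index
toy_junction <- function(g, u, v) {
  uni <- g$exon_union
  if (g$strand == "+")
    list(donor = uni$end[u], acceptor = uni$start[v],
         donor_exon = u, acceptor_exon = v)
  else
    list(donor = uni$start[u], acceptor = uni$end[v],
         donor_exon = u, acceptor_exon = v)
}

# small standard simulation shared by several tests (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(event_mix = c(SES = 3, MES = 2, A5SS = 2,
                                      A3SS = 2, MXE = 2, AFE = 1,
                                      ALE = 1),
                        depth = 1500L, seed = 11L)
      sim <- simulate_genome_and_models(cfg)
      reads <- simulate_reads(sim)
      cache <<- list(sim = sim, reads = reads)
    }
    cache
  }
})
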