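#' Build the combinatorial exon-exon junction database
#'
#' For each gene, enumerates one junction per ordered pair of distinct
#' `exon_union` members that do not overlap genomically, the upstream
#' member being transcriptionally 5' of the downstream one.  This
#' yields every known and in-silico-predicted junction representable
#' from the annotated exon boundaries: for a gene with n mutually
#' non-overlapping exons, exactly n(n-1)/2 junctions.  Overlapping
#' exons (alternative boundary variants of the same exonic region)
#' never form a junction with each other.
#'
#' Each junction record carries a mappable sequence: `flank_len` bases
#' ending at the donor followed by `flank_len` bases starting at the
#' acceptor, in transcript-strand orientation; flanks are truncated
#' (and flagged) when an exon is shorter than `flank_len`.  Junction
#' identity is `(chrom, strand, donor, acceptor)` genome-wide; on
#' collision the first assigned gene wins.
#'
#' @param models list of [gene_model()] objects.
#' @param genome named [Biostrings::DNAStringSet] of chromosomes.
#' @param flank_len flank length in nt; the default 70 pairs 75-nt
#'   reads with a 5-nt minimum anchor.
#' @param max_exons guard: genes whose exon union exceeds this size
#'   raise an error rather than enumerating pairs.
#' @return an object of class `junction_db`: a list with elements
#'   `junctions` (one data.frame row per junction: ids, coordinates,
#'   exon indices, source, sequence, flank widths, GT-AG advisory
#'   flag), `flank_len`, and `models`.
#' @export
build_combinatorial_db <- function(models, genome, flank_len = 70L,
                                   max_exons = 500L) {
  rows <- list()
  for (g in models) {
    uni <- g$exon_union
    n <- nrow(uni)
    if (n > max_exons)
      stop("gene '", g$gene_id, "' has ", n, " exons in union (max_exons = ",
           max_exons, ")")
    clen <- length(genome[[g$chrom]])
    if (is.null(clen)) stop("chromosome '", g$chrom, "' absent from genome")
    if (any(uni$end > clen))
      stop("exon beyond chromosome bounds in gene '", g$gene_id, "': ",
           paste0("[", uni$start[uni$end > clen][1], ",",
                  uni$end[uni$end > clen][1], ")"))
    if (n < 2L) next
    tex <- txc_exons(uni, g$strand)
    for (u in seq_len(n - 1L)) {
      for (v in seq((u + 1L), n)) {
        if (tex$e[u] > tex$s[v]) next  # overlapping variants: no junction
        rows[[length(rows) + 1L]] <-
          junction_row(g, uni, u, v, genome, flank_len, "combinatorial")
      }
    }
  }
  jdf <- if (length(rows)) do.call(rbind, rows) else empty_junction_df()
  # genome-wide identity: first assigned gene wins
  key <- paste(jdf$chrom, jdf$strand, jdf$donor, jdf$acceptor, sep = "|")
  jdf <- jdf[!duplicated(key), , drop = FALSE]
  rownames(jdf) <- NULL
  structure(list(junctions = jdf, flank_len = as.integer(flank_len),
                 models = models), class = "junction_db")
}

empty_junction_df <- function() {
  data.frame(junction_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             donor = integer(), acceptor = integer(),
             donor_exon = integer(), acceptor_exon = integer(),
             source = character(), seq = character(),
             flank_up = integer(), flank_down = integer(),
             truncated = logical(), gt_ag = logical())
}

junction_row <- function(g, uni, u, v, genome, flank_len, source) {
  strand <- g$strand
  up <- uni[u, ]; down <- uni[v, ]
  if (strand == "+") { donor <- up$end; acceptor <- down$start }
  else { donor <- up$start; acceptor <- down$end }
  lu <- up$end - up$start; ld <- down$end - down$start
  fu <- min(flank_len, lu); fd <- min(flank_len, ld)
  useq <- exon_seq(genome, g$chrom, strand, up$start, up$end)
  dseq <- exon_seq(genome, g$chrom, strand, down$start, down$end)
  seq <- paste0(substring(useq, lu - fu + 1L, lu), substring(dseq, 1L, fd))
  gtag <- junction_gt_ag(genome, g$chrom, strand, donor, acceptor)
  data.frame(junction_id = paste(g$gene_id, g$chrom, strand, donor, acceptor,
                                 sep = "|"),
             gene_id = g$gene_id, chrom = g$chrom, strand = strand,
             donor = donor, acceptor = acceptor,
             donor_exon = u, acceptor_exon = v, source = source,
             seq = seq, flank_up = fu, flank_down = fd,
             truncated = (fu < flank_len || fd < flank_len), gt_ag = gtag)
}

# advisory GT..AG check on the intron the junction spans
junction_gt_ag <- function(genome, chrom, strand, donor, acceptor) {
  intron <- if (strand == "+") c(donor, acceptor) else c(acceptor, donor)
  if (intron[2] - intron[1] < 4L) return(NA)
  s5 <- exon_seq(genome, chrom, strand, intron[1], intron[1] + 2L)
  s3 <- exon_seq(genome, chrom, strand, intron[2] - 2L, intron[2])
  if (strand == "+") s5 == "GT" && s3 == "AG"
  else {
    d5 <- exon_seq(genome, chrom, "-", intron[2] - 2L, intron[2])
    d3 <- exon_seq(genome, chrom, "-", intron[1], intron[1] + 2L)
    d5 == "GT" && d3 == "AG"
  }
}

#' @export
print.junction_db <- function(x, ...) {
  cat(sprintf("junction_db: %d junctions (%d combinatorial, %d de novo), flank_len %d\n",
              nrow(x$junctions), sum(x$junctions$source == "combinatorial"),
              sum(x$junctions$source == "denovo_import"), x$flank_len))
  invisible(x)
}

#' Export junction sequences as a mapping index FASTA
#'
#' Headers follow the grammar `gene|chrom|strand|donor|acceptor`
#' (bit-exact), so external aligner hits against this index can be
#' decoded back to junction records by [import_sam()].
#'
#' @param db a `junction_db`.
#' @param path output FASTA.
#' @export
export_junction_fasta <- function(db, path) {
  seqs <- Biostrings::DNAStringSet(db$junctions$seq)
  names(seqs) <- db$junctions$junction_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Import de novo junctions from a junction BED file
#'
#' Accepts TopHat-style `junctions.bed` (BED12 whose two blocks flank
#' the spliced-out gap) or 6-column junction BED (`start`..`end` is the
#' intron).  Junctions already present in the database are not
#' duplicated; new ones are added with `source = "denovo_import"` and
#' assigned to the gene whose span contains them on the matching
#' strand (none: `"intergenic"`); a junction contained in the spans of
#' two or more genes is assigned to neither and flagged ambiguous.
#'
#' @param db a `junction_db`.
#' @param path junction BED file.
#' @param genome named [Biostrings::DNAStringSet], used to extract the
#'   new junctions' flank sequences.
#' @return the updated `junction_db`; the number of ambiguous
#'   (dropped) imports is available as `attr(, "ambiguous")`.
#' @export
import_denovo_junctions <- function(db, path, genome) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) { attr(db, "ambiguous") <- 0L; return(db) }
  introns <- lapply(seq_along(gr), function(i) {
    r <- gr[i]
    strand <- as.character(GenomicRanges::strand(r))
    if (strand == "*") strand <- "+"
    blk <- S4Vectors::mcols(r)$blocks
    g0 <- GenomicRanges::start(r) - 1L
    if (!is.null(blk) && length(blk[[1]]) == 2L) {
      b <- blk[[1]]
      i0 <- g0 + GenomicRanges::end(b)[1]
      i1 <- g0 + GenomicRanges::start(b)[2] - 1L
    } else {
      i0 <- g0
      i1 <- GenomicRanges::end(r)
    }
    list(chrom = as.character(GenomicRanges::seqnames(r)), strand = strand,
         intron = c(i0, i1))
  })
  have <- paste(db$junctions$chrom, db$junctions$strand, db$junctions$donor,
                db$junctions$acceptor, sep = "|")
  spans <- lapply(db$models, gene_span)
  ambiguous <- 0L
  rows <- list()
  for (jx in introns) {
    donor <- if (jx$strand == "+") jx$intron[1] else jx$intron[2]
    acceptor <- if (jx$strand == "+") jx$intron[2] else jx$intron[1]
    key <- paste(jx$chrom, jx$strand, donor, acceptor, sep = "|")
    if (key %in% have) next
    owners <- names(db$models)[vapply(seq_along(db$models), function(i) {
      g <- db$models[[i]]
      g$chrom == jx$chrom && g$strand == jx$strand &&
        jx$intron[1] >= spans[[i]][1] && jx$intron[2] <= spans[[i]][2]
    }, logical(1))]
    if (length(owners) > 1L) { ambiguous <- ambiguous + 1L; next }
    gid <- if (length(owners) == 1L) owners else "intergenic"
    fl <- db$flank_len
    clen <- length(genome[[jx$chrom]])
    up <- c(max(0L, jx$intron[1] - fl), jx$intron[1])
    dn <- c(jx$intron[2], min(clen, jx$intron[2] + fl))
    sup <- exon_seq(genome, jx$chrom, "+", up[1], up[2])
    sdn <- exon_seq(genome, jx$chrom, "+", dn[1], dn[2])
    seq <- paste0(sup, sdn)
    fu <- nchar(sup); fd <- nchar(sdn)
    if (jx$strand == "-") {
      seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
      tmp <- fu; fu <- fd; fd <- tmp
    }
    de <- ae <- NA_integer_
    if (gid != "intergenic") {
      uni <- db$models[[gid]]$exon_union
      if (jx$strand == "+") {
        de <- match(donor, uni$end); ae <- match(acceptor, uni$start)
      } else {
        de <- match(donor, uni$start); ae <- match(acceptor, uni$end)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      junction_id = paste(gid, jx$chrom, jx$strand, donor, acceptor,
                          sep = "|"),
      gene_id = gid, chrom = jx$chrom, strand = jx$strand,
      donor = donor, acceptor = acceptor, donor_exon = de,
      acceptor_exon = ae, source = "denovo_import", seq = seq,
      flank_up = fu, flank_down = fd, truncated = (fu < fl || fd < fl),
      gt_ag = junction_gt_ag(genome, jx$chrom, jx$strand, donor, acceptor))
    have <- c(have, key)
  }
  if (length(rows))
    db$junctions <- rbind(db$junctions, do.call(rbind, rows))
  rownames(db$junctions) <- NULL
  attr(db, "ambiguous") <- ambiguous
  db
}

#' Write junctions as a TopHat-dialect BED12 track
#'
#' One BED12 line per junction with two `flank_len`-wide blocks
#' flanking the spliced-out gap; the score column carries the supplied
#' per-junction read count (junctions with zero reads are omitted when
#' `scores` is given, matching browser-track export conventions).
#'
#' @param db a `junction_db`.
#' @param path output BED file.
#' @param scores optional numeric read counts aligned to
#'   `db$junctions`; when supplied only junctions with a positive
#'   score are written.
#' @param track_name UCSC track header name, or `NULL` for none.
#' @export
write_junction_bed <- function(db, path, scores = NULL, track_name = NULL) {
  j <- db$junctions
  if (!is.null(scores)) {
    keep <- scores > 0
    j <- j[keep, , drop = FALSE]
    scores <- scores[keep]
  } else scores <- rep(0L, nrow(j))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf('track name="%s" itemRgb="Off"', track_name), con)
  for (i in seq_len(nrow(j))) {
    intron <- if (j$strand[i] == "+") c(j$donor[i], j$acceptor[i])
              else c(j$acceptor[i], j$donor[i])
    fu <- if (j$strand[i] == "+") j$flank_up[i] else j$flank_down[i]
    fd <- if (j$strand[i] == "+") j$flank_down[i] else j$flank_up[i]
    cs <- intron[1] - fu
    ce <- intron[2] + fd
    writeLines(paste(j$chrom[i], cs, ce, j$junction_id[i],
                     round(scores[i]), j$strand[i], cs, ce, "0", 2,
                     paste0(fu, ",", fd),
                     paste0(0, ",", intron[2] - cs), sep = "\t"), con)
  }
  invisible(path)
}
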