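#' Mapping parameters
#'
#' @param anchor_min minimum bases a junction read must carry on each
#'   side of the exon-exon boundary (default 5 nt).
#' @param trunc_step bases trimmed from the 3' end per truncation
#'   round during rescue (default 10).
#' @param trunc_min_len shortest read length still attempted; must be
#'   at least `2 * anchor_min`.
#' @param max_mismatches the internal mapper is exact-match; values
#'   above 0 are reserved for external aligners and ignored here with
#'   a warning.
#' @return a `mapping_params` list.
#' @export
mapping_params <- function(anchor_min = 5L, trunc_step = 10L,
                           trunc_min_len = 25L, max_mismatches = 0L) {
  stopifnot(trunc_step > 0L, anchor_min >= 1L)
  if (trunc_min_len < 2L * anchor_min)
    stop("trunc_min_len must be >= 2 * anchor_min")
  if (max_mismatches > 0L)
    warning("internal mapper is exact-match; max_mismatches ignored",
            call. = FALSE)
  structure(list(anchor_min = as.integer(anchor_min),
                 trunc_step = as.integer(trunc_step),
                 trunc_min_len = as.integer(trunc_min_len),
                 max_mismatches = 0L), class = "mapping_params")
}

# Genome annotation index used for read categorisation: per-chromosome
# exon intervals and gene spans.
genome_index <- function(models) {
  ex <- do.call(rbind, lapply(models, function(g)
    data.frame(chrom = g$chrom, start = g$exon_union$start,
               end = g$exon_union$end, gene_id = g$gene_id)))
  sp <- do.call(rbind, lapply(models, function(g) {
    s <- gene_span(g)
    data.frame(chrom = g$chrom, start = s[1], end = s[2],
               gene_id = g$gene_id)
  }))
  list(exons = ex, spans = sp)
}

categorize_position <- function(idx, chrom, start0, end0) {
  ex <- idx$exons
  hit <- which(ex$chrom == chrom & ex$start < end0 & ex$end > start0)
  if (length(hit)) return(list(target = "genome_exonic",
                               gene_id = ex$gene_id[hit[1]]))
  sp <- idx$spans
  hit <- which(sp$chrom == chrom & sp$start < end0 & sp$end > start0)
  if (length(hit)) return(list(target = "genome_intronic",
                               gene_id = sp$gene_id[hit[1]]))
  list(target = "genome_intergenic", gene_id = NA_character_)
}

#' Assign reads to junctions and genomic categories
#'
#' The internal exact-match mapper.  Each read is assigned to exactly
#' one target: a junction (when it matches one junction sequence
#' spanning the exon-exon boundary with at least `anchor_min` bases on
#' each side), else a genomic category (`genome_exonic` when the match
#' overlaps the exon union of any gene, `genome_intronic` within a
#' gene span but off-exon, `genome_intergenic` otherwise), else
#' `unmapped`.  A read matching two or more distinct junctions -- or,
#' failing that, two or more genomic loci -- equally well is unmapped
#' (unique-mapping policy).  Junction assignments take precedence over
#' genomic ones, so junction reads are never double-counted as exonic.
#'
#' @param reads a named [Biostrings::DNAStringSet], or the path of a
#'   FASTA/FASTQ file.
#' @param db a `junction_db` from [build_combinatorial_db()].
#' @param genome named [Biostrings::DNAStringSet].
#' @param params a [mapping_params()] list.
#' @return data.frame with one row per read: `read_id`, `target`,
#'   `junction_id`, `gene_id`, `chrom`, `pos` (0-based genomic start
#'   for genome targets), `read_strand`, `truncation_rounds`.
#' @export
map_reads <- function(reads, db, genome, params = mapping_params()) {
  reads <- as_read_set(reads)
  res <- match_reads_once(reads, db, genome, params)
  res$truncation_rounds <- 0L
  res
}

as_read_set <- function(reads) {
  if (is.character(reads) && length(reads) == 1L) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
    names(reads) <- sub("\\s.*$", "", names(reads))
  }
  stopifnot(methods::is(reads, "DNAStringSet"))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reads
}

# One exact-match pass at the reads' current lengths.  Works on
# preallocated atomic vectors; per-read work is O(hits).
match_reads_once <- function(reads, db, genome, params) {
  idx <- genome_index(db$models)
  n <- length(reads)
  target <- rep("unmapped", n)
  junction_id <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  chrom_out <- rep(NA_character_, n)
  pos_out <- rep(NA_integer_, n)
  strand_out <- rep(NA_character_, n)
  if (n > 0L) {
    widths <- Biostrings::width(reads)
    jid <- db$junctions$junction_id
    jgene <- db$junctions$gene_id
    jchrom <- db$junctions$chrom
    jflank_up <- db$junctions$flank_up
    jseqs <- db$junctions$seq
    sep <- strrep("N", max(widths) + 1L)
    jcat <- Biostrings::DNAString(paste(jseqs, collapse = sep))
    # 1-based start of each junction sequence inside the concatenation
    joff <- cumsum(c(1L, utils::head(nchar(jseqs) + nchar(sep), -1L)))
    for (w in unique(widths)) {
      if (w < 2L * params$anchor_min) next  # stays unmapped
      sel <- which(widths == w)
      pd <- Biostrings::PDict(reads[sel])
      jm <- Biostrings::startIndex(Biostrings::matchPDict(pd, jcat))
      jhits <- lapply(seq_along(sel), function(k) {
        ss <- jm[[k]]
        if (is.null(ss) || length(ss) == 0L) return(integer(0))
        jidx <- findInterval(ss, joff)
        o <- ss - joff[jidx] + 1L           # 1-based offset within jseq
        bpos <- jflank_up[jidx]             # boundary after this many bases
        span <- o <= bpos - params$anchor_min + 1L &
          o + w - 1L >= bpos + params$anchor_min
        unique(jidx[span])
      })
      # genome hits (both strands), as "chrom:strand:pos0" keys
      ghits <- vector("list", length(sel))
      for (chrom in names(genome)) {
        chr <- genome[[chrom]]
        clen <- length(chr)
        fst <- Biostrings::startIndex(Biostrings::matchPDict(pd, chr))
        rst <- Biostrings::startIndex(
          Biostrings::matchPDict(pd, Biostrings::reverseComplement(chr)))
        for (k in seq_along(sel)) {
          if (!is.null(fst[[k]]) && length(fst[[k]]))
            ghits[[k]] <- c(ghits[[k]],
                            paste(chrom, "+", fst[[k]] - 1L, sep = ":"))
          if (!is.null(rst[[k]]) && length(rst[[k]]))
            ghits[[k]] <- c(ghits[[k]],
                            paste(chrom, "-", clen - (rst[[k]] - 1L) - w,
                                  sep = ":"))
        }
      }
      for (k in seq_along(sel)) {
        i <- sel[k]
        jh <- jhits[[k]]
        if (length(jh) == 1L) {
          target[i] <- "junction"
          junction_id[i] <- jid[jh]
          gene_id[i] <- jgene[jh]
          chrom_out[i] <- jchrom[jh]
          next
        }
        if (length(jh) > 1L) next  # ambiguous junction hit -> unmapped
        gh <- unique(ghits[[k]])
        if (length(gh) != 1L) next # none or multi-locus -> unmapped
        parts <- strsplit(gh, ":", fixed = TRUE)[[1]]
        start0 <- as.integer(parts[3])
        cat <- categorize_position(idx, parts[1], start0, start0 + w)
        target[i] <- cat$target
        gene_id[i] <- cat$gene_id
        chrom_out[i] <- parts[1]
        pos_out[i] <- start0
        strand_out[i] <- parts[2]
      }
    }
  }
  data.frame(read_id = if (n) names(reads) else character(0),
             target = target, junction_id = junction_id, gene_id = gene_id,
             chrom = chrom_out, pos = pos_out, read_strand = strand_out,
             stringsAsFactors = FALSE)
}

#' Rescue unmapped reads by iterative 3' truncation
#'
#' Reads that failed to map at full length -- typically reads spanning
#' three or more exons, which align to no single junction window --
#' are trimmed from their 3' end in steps of `trunc_step` bases and
#' remapped after each trim, stopping at the first successful
#' assignment or once the trimmed length would fall below
#' `trunc_min_len`.  `truncation_rounds` records the number of trims
#' used (or attempted, for reads that never map).
#'
#' @param reads named [Biostrings::DNAStringSet] of previously
#'   unmapped reads, at their original full length.
#' @inheritParams map_reads
#' @return data.frame as in [map_reads()].
#' @export
truncate_and_rescue <- function(reads, db, genome, params = mapping_params()) {
  reads <- as_read_set(reads)
  n <- length(reads)
  out <- data.frame(read_id = names(reads), target = rep("unmapped", n),
                    junction_id = NA_character_, gene_id = NA_character_,
                    chrom = NA_character_, pos = NA_integer_,
                    read_strand = NA_character_, truncation_rounds = 0L,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  pending <- seq_len(n)
  r <- 0L
  repeat {
    r <- r + 1L
    widths <- Biostrings::width(reads)[pending]
    new_w <- widths - r * params$trunc_step
    doable <- new_w >= params$trunc_min_len
    if (!any(doable)) { r <- r - 1L; break }
    idx <- pending[doable]
    trimmed <- Biostrings::subseq(reads[idx], start = 1L,
                                  width = Biostrings::width(reads)[idx] -
                                    r * params$trunc_step)
    res <- match_reads_once(trimmed, db, genome, params)
    mapped <- which(res$target != "unmapped")
    if (length(mapped)) {
      ii <- idx[mapped]
      out[ii, c("target", "junction_id", "gene_id", "chrom", "pos",
                "read_strand")] <-
        res[mapped, c("target", "junction_id", "gene_id", "chrom", "pos",
                      "read_strand")]
      out$truncation_rounds[ii] <- r
      pending <- setdiff(pending, ii)
    }
    out$truncation_rounds[pending] <- r
    if (length(pending) == 0L) break
  }
  out
}

#' Import external alignments (SAM/BAM)
#'
#' Decodes alignments produced by an external aligner against the
#' genome and/or the junction-index FASTA exported by
#' [export_junction_fasta()].  Reference names matching the index
#' grammar `gene|chrom|strand|donor|acceptor` are resolved to junction
#' assignments directly; genome alignments with a single N-CIGAR gap
#' whose coordinates equal a database junction's (donor, acceptor) are
#' junction assignments too; other genome alignments are categorised
#' as in [map_reads()].  Secondary and supplementary alignments are
#' ignored; records whose reference matches neither the genome nor the
#' grammar are skipped and counted (`attr(, "skipped")`).
#'
#' @param path SAM or BAM file.
#' @param db a `junction_db`.
#' @param genome named [Biostrings::DNAStringSet].
#' @return data.frame as in [map_reads()].
#' @export
import_sam <- function(path, db, genome) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "strand"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  idx <- genome_index(db$models)
  keys <- paste(db$junctions$chrom, db$junctions$strand, db$junctions$donor,
                db$junctions$acceptor, sep = "|")
  out <- data.frame(read_id = b$qname, target = rep("unmapped", n),
                    junction_id = NA_character_, gene_id = NA_character_,
                    chrom = NA_character_, pos = NA_integer_,
                    read_strand = NA_character_, truncation_rounds = 0L,
                    stringsAsFactors = FALSE)
  skipped <- 0L
  drop <- logical(n)
  grammar <- "^[^|]+\\|[^|]+\\|[+-]\\|[0-9]+\\|[0-9]+$"
  for (i in seq_len(n)) {
    fl <- b$flag[i]
    if (bitwAnd(fl, 256L) > 0L || bitwAnd(fl, 2048L) > 0L) {
      drop[i] <- TRUE
      next
    }
    if (bitwAnd(fl, 4L) > 0L) next  # unmapped record
    rn <- as.character(b$rname[i])
    if (grepl(grammar, rn)) {
      j <- match(rn, db$junctions$junction_id)
      if (is.na(j)) {
        # decode coordinates; the gene field may differ from ours
        f <- strsplit(rn, "|", fixed = TRUE)[[1]]
        j <- match(paste(f[2], f[3], f[4], f[5], sep = "|"), keys)
      }
      if (is.na(j)) { skipped <- skipped + 1L; drop[i] <- TRUE; next }
      out$target[i] <- "junction"
      out$junction_id[i] <- db$junctions$junction_id[j]
      out$gene_id[i] <- db$junctions$gene_id[j]
      out$chrom[i] <- db$junctions$chrom[j]
      next
    }
    if (!rn %in% names(genome)) { skipped <- skipped + 1L; drop[i] <- TRUE; next }
    cig <- b$cigar[i]
    pos0 <- b$pos[i] - 1L
    gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cig, pos = b$pos[i], ops = "N")[[1]]
    if (length(gaps) >= 1L) {
      g0 <- IRanges::start(gaps)[1] - 1L
      g1 <- IRanges::end(gaps)[1]
      j <- match(paste(rn, "+", g0, g1, sep = "|"), keys)
      if (is.na(j)) j <- match(paste(rn, "-", g1, g0, sep = "|"), keys)
      if (!is.na(j)) {
        out$target[i] <- "junction"
        out$junction_id[i] <- db$junctions$junction_id[j]
        out$gene_id[i] <- db$junctions$gene_id[j]
        out$chrom[i] <- rn
        next
      }
    }
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
    cat <- categorize_position(idx, rn, pos0, pos0 + w)
    out$target[i] <- cat$target
    out$gene_id[i] <- cat$gene_id
    out$chrom[i] <- rn
    out$pos[i] <- pos0
    out$read_strand[i] <- as.character(b$strand[i])
  }
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (skipped > 0L)
    message(skipped, " record(s) with unresolvable reference skipped")
  attr(out, "skipped") <- skipped
  out
}
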