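#' Gene model containers
#'
#' A `gene_model` bundles, for one gene, every annotated isoform (an
#' ordered exon chain with an optional CDS) together with the
#' non-redundant union of all distinct exon intervals across isoforms
#' (`exon_union`).  Exons differing in either boundary are distinct
#' members of the union -- this is what makes alternative 5'/3' splice
#' sites representable downstream.  All coordinates are 0-based
#' half-open; `exon_union` is sorted 5' to 3' in transcription order.
#'
#' @param gene_id character scalar.
#' @param chrom,strand chromosome name and strand (`"+"` or `"-"`).
#' @param isoforms named list of isoforms built with [isoform()].
#' @param sources character vector of provenance labels, recycled over
#'   isoforms when building the exon union.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, isoforms, sources = "user") {
  stopifnot(length(gene_id) == 1L, strand %in% c("+", "-"), length(isoforms) >= 1L)
  if (is.null(names(isoforms)))
    names(isoforms) <- vapply(isoforms, function(x) x$id, character(1))
  sources <- rep_len(sources, length(isoforms))
  ex <- do.call(rbind, lapply(seq_along(isoforms), function(i) {
    cbind(isoforms[[i]]$exons[, c("start", "end")], sources = sources[i])
  }))
  key <- paste(ex$start, ex$end)
  src <- vapply(split(ex$sources, key), function(s)
    paste(sort(unique(s)), collapse = ","), character(1))
  uni <- unique(ex[, c("start", "end")])
  uni$sources <- src[paste(uni$start, uni$end)]
  o <- if (strand == "+") order(uni$start, uni$end) else order(-uni$end, -uni$start)
  uni <- uni[o, , drop = FALSE]
  rownames(uni) <- NULL
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 isoforms = isoforms, exon_union = uni),
            class = "gene_model")
}

#' @describeIn gene_model one isoform: an ordered exon chain in
#'   transcription order with an optional transcript-relative CDS.
#'   `cds_start` is the 0-based offset of the first base of the start
#'   codon; `cds_end` the offset one past the last annotated CDS base.
#' @param id isoform identifier.
#' @param exons data.frame with `start`,`end` columns (0-based
#'   half-open), rows in transcription order.
#' @param cds_start,cds_end transcript-relative CDS bounds or `NA`.
#' @param cds_inferred logical flag: `TRUE` when the CDS was inferred
#'   from the longest ORF rather than annotated.
#' @export
isoform <- function(id, exons, cds_start = NA_integer_, cds_end = NA_integer_,
                    cds_inferred = FALSE) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  stopifnot(all(exons$start < exons$end))
  lens <- exons$end - exons$start
  if (!is.na(cds_start) && cds_start >= sum(lens) - 2L)
    stop("cds_start of '", id, "' too close to transcript end")
  list(id = id, exons = exons,
       cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
       cds_inferred = isTRUE(cds_inferred))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d isoform(s), %d exon(s) in union\n",
              x$gene_id, x$chrom, x$strand, length(x$isoforms),
              nrow(x$exon_union)))
  invisible(x)
}

# total mature (spliced) length of an isoform
isoform_length <- function(iso) sum(iso$exons$end - iso$exons$start)

# genomic span [start, end) of a gene model
gene_span <- function(g) {
  c(min(g$exon_union$start), max(g$exon_union$end))
}

#' Pick the longest isoform of a gene
#'
#' Returns the isoform with maximal summed exon (mature) length; ties
#' are broken by lexicographically smallest isoform id.  With
#' `cds_only = TRUE` only isoforms carrying an annotated or inferred
#' CDS are considered (the backbone used for PTC prediction).
#'
#' @param g a [gene_model()].
#' @param cds_only restrict to CDS-bearing isoforms.
#' @return an isoform, or `NULL` if `cds_only` filters all out.
#' @export
longest_isoform <- function(g, cds_only = FALSE) {
  isos <- g$isoforms
  if (cds_only) isos <- Filter(function(i) !is.na(i$cds_start), isos)
  if (length(isos) == 0L) return(NULL)
  lens <- vapply(isos, isoform_length, numeric(1))
  ids <- vapply(isos, function(i) i$id, character(1))
  isos[[order(-lens, ids)[1]]]
}

# ---------------------------------------------------------------------
# Readers

#' Load gene models from an annotation file
#'
#' Reads transcript models in one of three dialects and assembles one
#' [gene_model()] per gene.  GTF (1-based closed) coordinates are
#' converted to the internal 0-based half-open convention at the
#' boundary; BED12 and refFlat are already 0-based half-open.  CDS
#' start (and end) are recorded when the dialect provides them (GTF CDS
#' records, BED12 thick range, refFlat cdsStart/cdsEnd).
#'
#' Transcripts whose exons mix strands or chromosomes are rejected with
#' a warning.  A record that cannot be parsed raises an error naming
#' the offending line.
#'
#' @param path annotation file.
#' @param dialect one of `"gtf"`, `"bed12"`, `"refflat"`.
#' @param source provenance label attached to every exon (defaults to
#'   the file's base name).
#' @return list of [gene_model()] objects, named by gene id.
#' @export
load_gene_models <- function(path, dialect = c("gtf", "bed12", "refflat"),
                             source = basename(path)) {
  dialect <- match.arg(dialect)
  tx <- switch(dialect,
               gtf = read_gtf_transcripts(path),
               bed12 = read_bed12_transcripts(path),
               refflat = read_refflat_transcripts(path))
  assemble_gene_models(tx, source)
}

# One row per transcript: gene_id, tx_id, chrom, strand plus list
# columns of exon starts/ends (tx order) and cds tx offsets.
assemble_gene_models <- function(tx, source) {
  keep <- vapply(seq_len(nrow(tx)), function(i) {
    ok <- length(unique(tx$chrom_all[[i]])) == 1L &&
      length(unique(tx$strand_all[[i]])) == 1L
    if (!ok) warning("transcript '", tx$tx_id[i],
                     "' has exons on mixed strands/chromosomes; rejected",
                     call. = FALSE)
    ok
  }, logical(1))
  tx <- tx[keep, , drop = FALSE]
  out <- list()
  for (gid in unique(tx$gene_id)) {
    sub <- tx[tx$gene_id == gid, , drop = FALSE]
    combos <- unique(paste(sub$chrom, sub$strand))
    for (k in seq_along(combos)) {
      ss <- sub[paste(sub$chrom, sub$strand) == combos[k], , drop = FALSE]
      gid_k <- if (k == 1L) gid else paste0(gid, "_", k)
      if (k > 1L)
        warning("gene '", gid, "' spans multiple chromosome/strand ",
                "combinations; split as '", gid_k, "'", call. = FALSE)
      isos <- lapply(seq_len(nrow(ss)), function(i) {
        isoform(ss$tx_id[i],
                data.frame(start = ss$starts[[i]], end = ss$ends[[i]]),
                cds_start = ss$cds_start[i], cds_end = ss$cds_end[i])
      })
      names(isos) <- ss$tx_id
      out[[gid_k]] <- gene_model(gid_k, ss$chrom[1], ss$strand[1], isos,
                                 sources = source)
    }
  }
  out
}

read_gtf_transcripts <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  bad <- body[vapply(strsplit(lines[body], "\t", fixed = TRUE), length,
                     integer(1)) < 9L]
  if (length(bad))
    stop("malformed GTF record at line ", bad[1], " of ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!all(c("type", "gene_id", "transcript_id") %in% names(md)))
    stop("GTF at ", path, " lacks gene_id/transcript_id attributes")
  ex <- gr[md$type == "exon"]
  cds <- gr[md$type == "CDS"]
  build_tx_table(ex, cds)
}

# Shared assembly from exon/CDS GRanges (1-based closed in, 0-based out)
build_tx_table <- function(ex, cds) {
  exd <- data.frame(tx_id = as.character(S4Vectors::mcols(ex)$transcript_id),
                    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
                    chrom = as.character(GenomicRanges::seqnames(ex)),
                    strand = as.character(GenomicRanges::strand(ex)),
                    start = GenomicRanges::start(ex) - 1L,
                    end = GenomicRanges::end(ex))
  cdsd <- if (length(cds)) {
    data.frame(tx_id = as.character(S4Vectors::mcols(cds)$transcript_id),
               start = GenomicRanges::start(cds) - 1L,
               end = GenomicRanges::end(cds))
  } else data.frame(tx_id = character(), start = integer(), end = integer())
  ids <- unique(exd$tx_id)
  rows <- lapply(ids, function(tid) {
    e <- exd[exd$tx_id == tid, , drop = FALSE]
    strand <- e$strand[1]
    o <- if (strand == "+") order(e$start) else order(-e$start)
    e <- e[o, , drop = FALSE]
    cs <- ce <- NA_integer_
    cc <- cdsd[cdsd$tx_id == tid, , drop = FALSE]
    if (nrow(cc)) {
      chain <- data.frame(start = e$start, end = e$end)
      if (strand == "+") {
        first <- min(cc$start); last <- max(cc$end) - 1L
      } else {
        first <- max(cc$end) - 1L; last <- min(cc$start)
      }
      cs <- genomic_to_tx(chain, strand, first)
      ce <- genomic_to_tx(chain, strand, last) + 1L
    }
    list(gene_id = e$gene_id[1], tx_id = tid, chrom = e$chrom[1],
         strand = strand, starts = list(e$start), ends = list(e$end),
         chrom_all = list(e$chrom), strand_all = list(e$strand),
         cds_start = cs, cds_end = ce)
  })
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r$gene_id, tx_id = r$tx_id, chrom = r$chrom,
               strand = r$strand, starts = I(r$starts), ends = I(r$ends),
               chrom_all = I(r$chrom_all), strand_all = I(r$strand_all),
               cds_start = r$cds_start, cds_end = r$cds_end)))
}

read_bed12_transcripts <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED12 record in ", path,
                                          ": ", conditionMessage(e)))
  rows <- lapply(seq_along(gr), function(i) {
    r <- gr[i]
    blk <- S4Vectors::mcols(r)$blocks[[1]]
    g0 <- GenomicRanges::start(r) - 1L
    starts <- g0 + GenomicRanges::start(blk) - 1L
    ends <- starts + GenomicRanges::width(blk)
    strand <- as.character(GenomicRanges::strand(r))
    if (strand == "*") strand <- "+"
    o <- if (strand == "+") order(starts) else order(-starts)
    starts <- starts[o]; ends <- ends[o]
    chain <- data.frame(start = starts, end = ends)
    cs <- ce <- NA_integer_
    th <- S4Vectors::mcols(r)$thick
    if (!is.null(th) && IRanges::width(th) > 0 &&
        IRanges::width(th) != IRanges::width(GenomicRanges::ranges(r))) {
      t0 <- IRanges::start(th) - 1L; t1 <- IRanges::end(th) - 1L
      first <- if (strand == "+") t0 else t1
      last <- if (strand == "+") t1 else t0
      cs <- genomic_to_tx(chain, strand, first)
      ce <- genomic_to_tx(chain, strand, last) + 1L
    }
    nm <- as.character(S4Vectors::mcols(r)$name)
    data.frame(gene_id = nm, tx_id = nm,
               chrom = as.character(GenomicRanges::seqnames(r)),
               strand = strand, starts = I(list(starts)),
               ends = I(list(ends)),
               chrom_all = I(list(rep(as.character(GenomicRanges::seqnames(r)),
                                      length(starts)))),
               strand_all = I(list(rep(strand, length(starts)))),
               cds_start = cs, cds_end = ce)
  })
  do.call(rbind, rows)
}

read_refflat_transcripts <- function(path) {
  rf <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("geneName", "name", "chrom", "strand",
                                        "txStart", "txEnd", "cdsStart",
                                        "cdsEnd", "exonCount", "exonStarts",
                                        "exonEnds"))
  rows <- lapply(seq_len(nrow(rf)), function(i) {
    starts <- as.integer(strsplit(rf$exonStarts[i], ",")[[1]])
    ends <- as.integer(strsplit(rf$exonEnds[i], ",")[[1]])
    if (length(starts) != rf$exonCount[i] || any(is.na(starts)) ||
        any(is.na(ends)))
      stop("malformed refFlat record at line ", i, " of ", path)
    strand <- rf$strand[i]
    o <- if (strand == "+") order(starts) else order(-starts)
    starts <- starts[o]; ends <- ends[o]
    chain <- data.frame(start = starts, end = ends)
    cs <- ce <- NA_integer_
    if (rf$cdsStart[i] < rf$cdsEnd[i]) {
      first <- if (strand == "+") rf$cdsStart[i] else rf$cdsEnd[i] - 1L
      last <- if (strand == "+") rf$cdsEnd[i] - 1L else rf$cdsStart[i]
      cs <- genomic_to_tx(chain, strand, first)
      ce <- genomic_to_tx(chain, strand, last) + 1L
    }
    data.frame(gene_id = rf$geneName[i], tx_id = rf$name[i],
               chrom = rf$chrom[i], strand = strand,
               starts = I(list(starts)), ends = I(list(ends)),
               chrom_all = I(list(rep(rf$chrom[i], length(starts)))),
               strand_all = I(list(rep(strand, length(starts)))),
               cds_start = cs, cds_end = ce)
  })
  do.call(rbind, rows)
}

#' Write gene models to GTF
#'
#' Emits exon records (and CDS records for CDS-bearing isoforms) in
#' 1-based closed GTF coordinates with `gene_id`/`transcript_id`
#' attributes.  Re-loading the file yields identical exon coordinate
#' sets and CDS bounds.
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @export
write_gtf <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in models) {
    for (iso in g$isoforms) {
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                          g$gene_id, iso$id)
      ex <- iso$exons
      for (i in seq_len(nrow(ex)))
        writeLines(paste(g$chrom, "splicejudge", "exon", ex$start[i] + 1L,
                         ex$end[i], ".", g$strand, ".", attr_str,
                         sep = "\t"), con)
      if (!is.na(iso$cds_start) && !is.na(iso$cds_end)) {
        blocks <- tx_interval_to_blocks(ex, g$strand, iso$cds_start,
                                        iso$cds_end)
        for (i in seq_len(nrow(blocks)))
          writeLines(paste(g$chrom, "splicejudge", "CDS",
                           blocks$start[i] + 1L, blocks$end[i], ".",
                           g$strand, "0", attr_str, sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

# Genomic blocks (0-based half-open, genomic order) covered by a
# transcript-relative interval [from, to) through an exon chain.
tx_interval_to_blocks <- function(exons, strand, from, to) {
  lens <- exons$end - exons$start
  cum <- c(0L, cumsum(lens))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    a <- max(from, cum[i]); b <- min(to, cum[i + 1L])
    if (a >= b) next
    w1 <- a - cum[i]; w2 <- b - cum[i]
    blk <- if (strand == "+")
      c(exons$start[i] + w1, exons$start[i] + w2)
    else c(exons$end[i] - w2, exons$end[i] - w1)
    out[[length(out) + 1L]] <- blk
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end")
  df[order(df$start), , drop = FALSE]
}

#' Merge gene models from multiple repositories
#'
#' Reconciles gene identity by exact `gene_id` match first, then by
#' single-linkage clustering of genes whose exons overlap by at least
#' one base on the same strand.  Per merged gene, `exon_union` is the
#' set-union of exact exon intervals from all sources (provenance
#' retained per exon); the operation is commutative and idempotent on
#' the union.  Overlapping genes on opposite strands are never merged.
#'
#' @param models_by_source list of lists of [gene_model()] (one inner
#'   list per repository).
#' @return list of merged [gene_model()] objects.
#' @export
merge_repositories <- function(models_by_source) {
  pool <- unlist(models_by_source, recursive = FALSE, use.names = FALSE)
  if (length(pool) == 0L) return(list())
  n <- length(pool)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  join <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  ids <- vapply(pool, function(g) g$gene_id, character(1))
  strands <- vapply(pool, function(g) g$strand, character(1))
  chroms <- vapply(pool, function(g) g$chrom, character(1))
  # pass 1: identical gene ids (same chrom+strand)
  for (id in unique(ids)) {
    idx <- which(ids == id)
    for (cs in unique(paste(chroms[idx], strands[idx]))) {
      sub <- idx[paste(chroms[idx], strands[idx]) == cs]
      if (length(sub) > 1L) for (k in sub[-1]) join(sub[1], k)
    }
    if (length(unique(strands[idx])) > 1L)
      warning("gene id '", id, "' appears on opposite strands; ",
              "kept as separate genes", call. = FALSE)
  }
  # pass 2: exonic overlap, same strand
  gr <- GenomicRanges::GRanges(
    seqnames = rep(chroms, vapply(pool, function(g) nrow(g$exon_union),
                                  integer(1))),
    ranges = IRanges::IRanges(
      start = unlist(lapply(pool, function(g) g$exon_union$start)) + 1L,
      end = unlist(lapply(pool, function(g) g$exon_union$end))),
    strand = rep(strands, vapply(pool, function(g) nrow(g$exon_union),
                                 integer(1))))
  owner <- rep(seq_len(n), vapply(pool, function(g) nrow(g$exon_union),
                                  integer(1)))
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = FALSE,
                                      drop.self = TRUE)
  for (h in seq_along(hits)) {
    a <- owner[S4Vectors::queryHits(hits)[h]]
    b <- owner[S4Vectors::subjectHits(hits)[h]]
    if (a != b) join(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- pool[roots == r]
    isos <- list()
    srcs <- character(0)
    for (m in members) for (nm in names(m$isoforms)) {
      key <- nm
      while (key %in% names(isos)) key <- paste0(key, "'")
      isos[[key]] <- m$isoforms[[nm]]
      isos[[key]]$id <- key
      srcs <- c(srcs, paste(vapply(strsplit(m$exon_union$sources[1], ","),
                                   identity, character(1))[1]))
    }
    gid <- members[[1]]$gene_id
    while (gid %in% names(out)) gid <- paste0(gid, "_2")
    merged <- gene_model(gid, members[[1]]$chrom, members[[1]]$strand, isos,
                         sources = srcs)
    # recompute provenance from the member unions (exact intervals)
    allex <- do.call(rbind, lapply(members, function(m) m$exon_union))
    key <- paste(allex$start, allex$end)
    src <- vapply(split(allex$sources, key), function(s)
      paste(sort(unique(unlist(strsplit(s, ",")))), collapse = ","),
      character(1))
    merged$exon_union$sources <-
      src[paste(merged$exon_union$start, merged$exon_union$end)]
    out[[gid]] <- merged
  }
  out
}
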