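#' Read a per-base conservation track
#'
#' Loads fixed-step WIG or bedGraph text (the distribution formats of
#' phastCons-style scores) into per-chromosome numeric vectors.
#' Positions the track does not cover are `NA` -- missing, never 0 --
#' and queries beyond the track return `NA` likewise.
#'
#' @param path WIG or bedGraph file.
#' @return a `cons_track`: named list of numeric vectors (index i =
#'   0-based position i-1).
#' @export
read_conservation_track <- function(path) {
  fmt <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
    "bedGraph" else "wig"
  gr <- rtracklayer::import(path, format = fmt)
  out <- list()
  for (chrom in unique(as.character(GenomicRanges::seqnames(gr)))) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    v <- rep(NA_real_, max(GenomicRanges::end(sub)))
    for (i in seq_along(sub))
      v[GenomicRanges::start(sub)[i]:GenomicRanges::end(sub)[i]] <-
        S4Vectors::mcols(sub)$score[i]
    out[[chrom]] <- v
  }
  structure(out, class = "cons_track")
}

#' Write a conservation track as fixed-step WIG
#'
#' @param track a `cons_track` (named list of per-chromosome numeric
#'   vectors; `NA` runs are omitted from the file).
#' @param path output file.
#' @export
write_conservation_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    v <- track[[chrom]]
    ok <- !is.na(v)
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1", chrom,
                         starts[r]), con)
      writeLines(format(v[starts[r]:ends[r]], trim = TRUE, digits = 6), con)
    }
  }
  invisible(path)
}

# scores at 0-based positions; out-of-range -> NA
track_values <- function(track, chrom, pos0) {
  v <- track[[chrom]]
  if (is.null(v)) return(rep(NA_real_, length(pos0)))
  i <- pos0 + 1L
  out <- rep(NA_real_, length(pos0))
  ok <- i >= 1L & i <= length(v)
  out[ok] <- v[i[ok]]
  out
}

# Positions (0-based, transcript orientation, NA-padded) of a window of
# `len` bases anchored at a genomic boundary.  `where` = "before":
# the len bases 5'-adjacent (transcript sense) to the boundary;
# "after": the len bases starting at it.  `limit` = [lo, hi) clips to
# an allowed interval (exon or intron extent); clipped positions are NA
# at the far-from-boundary side so windows stay boundary-aligned.
anchored_window <- function(boundary, len, where, strand, limit) {
  if (strand == "+") {
    pos <- if (where == "before") seq(boundary - len, boundary - 1L)
           else seq(boundary, boundary + len - 1L)
  } else {
    pos <- if (where == "before") seq(boundary + len - 1L, boundary)
           else seq(boundary - 1L, boundary - len)
  }
  pos[pos < limit[1] | pos >= limit[2]] <- NA_integer_
  pos
}

#' Conservation meta-profile around skipped (cassette) exons
#'
#' For each anchor set, averages per-base scores over a fixed window
#' laid out in transcript orientation: the last `exon_flank` nt of the
#' upstream exon, the `intron_flank` nt of upstream intron adjacent to
#' the cassette, the first and last `exon_flank` nt of the cassette
#' exon, the `intron_flank` nt of downstream intron adjacent to the
#' cassette, and the first `exon_flank` nt of the downstream exon
#' (total `4*exon_flank + 2*intron_flank` positions).  Exons or
#' introns shorter than the window contribute their available
#' positions only; means are taken per position over anchors with
#' non-missing data.
#'
#' @param anchor_sets named list of data.frames, one per event set
#'   (e.g. PTC+/PTC- exclusion/inclusion, unregulated), each with
#'   columns `chrom`, `strand`, `up_start`, `up_end`, `cas_start`,
#'   `cas_end`, `down_start`, `down_end` (genomic 0-based half-open;
#'   "up" = transcriptionally upstream flanking exon).
#' @param track a `cons_track`.
#' @param exon_flank,intron_flank window extents in nt (defaults 25
#'   and 75).
#' @return named list of `cons_profile` objects (`label`,
#'   `n_anchors`, `segments`, `mean_score`).
#' @export
profile_ses <- function(anchor_sets, track, exon_flank = 25L,
                        intron_flank = 75L) {
  if (is.null(names(anchor_sets))) stop("anchor_sets must be named")
  lapply(stats::setNames(names(anchor_sets), names(anchor_sets)),
         function(lab) {
    a <- anchor_sets[[lab]]
    if (is.null(a) || nrow(a) == 0L) stop("empty anchor set '", lab, "'")
    rows <- t(vapply(seq_len(nrow(a)), function(i)
      ses_window_scores(a[i, ], track, exon_flank, intron_flank),
      numeric(4L * exon_flank + 2L * intron_flank)))
    structure(list(label = lab, n_anchors = nrow(a),
                   segments = rep(c("up_exon", "up_intron", "cas_5p",
                                    "cas_3p", "down_intron", "down_exon"),
                                  times = c(exon_flank, intron_flank,
                                            exon_flank, exon_flank,
                                            intron_flank, exon_flank)),
                   mean_score = colMeans(rows, na.rm = TRUE),
                   baseline_subtracted = FALSE),
              class = "cons_profile")
  })
}

ses_window_scores <- function(a, track, ef, inf) {
  strand <- a$strand
  fwd <- strand == "+"
  # transcript-sense boundaries of the three exons
  up_end_b   <- if (fwd) a$up_end else a$up_start     # 3' end of upstream exon
  cas_start_b <- if (fwd) a$cas_start else a$cas_end  # 5' start of cassette
  cas_end_b  <- if (fwd) a$cas_end else a$cas_start
  down_start_b <- if (fwd) a$down_start else a$down_end
  up_lim <- c(a$up_start, a$up_end)
  cas_lim <- c(a$cas_start, a$cas_end)
  down_lim <- c(a$down_start, a$down_end)
  up_intron_lim <- if (fwd) c(a$up_end, a$cas_start) else c(a$cas_end, a$up_start)
  down_intron_lim <- if (fwd) c(a$cas_end, a$down_start) else c(a$down_start, a$cas_start)
  pos <- c(anchored_window(up_end_b, ef, "before", strand, up_lim),
           anchored_window(cas_start_b, inf, "before", strand, up_intron_lim),
           anchored_window(cas_start_b, ef, "after", strand, cas_lim),
           anchored_window(cas_end_b, ef, "before", strand, cas_lim),
           anchored_window(cas_end_b, inf, "after", strand, down_intron_lim),
           anchored_window(down_start_b, ef, "after", strand, down_lim))
  out <- rep(NA_real_, length(pos))
  ok <- !is.na(pos)
  out[ok] <- track_values(track, a$chrom, pos[ok])
  out
}

#' Baseline-subtracted conservation profile around PTCs
#'
#' Averages scores in a window of `halfwin` nt on each side of each
#' PTC (anchored at the first base of the stop codon, transcript
#' orientation), clipped at the boundaries of the exon holding the
#' stop -- scores never extend into introns and individual windows may
#' be shorter than the full extent.  A seeded random sample of
#' expressed exons (each anchored at its centre base, clipped at its
#' own boundaries) provides the positional baseline, which is
#' subtracted.
#'
#' @param anchors data.frame with `chrom`, `strand`, `gpos` (genomic
#'   0-based position of the stop's first base), `exon_start`,
#'   `exon_end`.
#' @param track a `cons_track`.
#' @param baseline_exons data.frame of expressed exons (`chrom`,
#'   `strand`, `start`, `end`) to sample the baseline from.
#' @param n_baseline baseline sample size (default 4000, capped at
#'   the number of available exons).
#' @param seed RNG seed for the baseline sample (default 1729).
#' @param halfwin half-window in nt (default 100).
#' @return a `cons_profile` with `mean_score` (baseline-subtracted),
#'   `raw`, `baseline`, `n_anchors`, `n_skipped`.
#' @export
profile_ptc <- function(anchors, track, baseline_exons, n_baseline = 4000L,
                        seed = 1729L, halfwin = 100L) {
  if (nrow(anchors) == 0L) stop("empty PTC anchor set")
  win <- function(chrom, strand, center, lim) {
    pos <- if (strand == "+") seq(center - halfwin, center + halfwin)
           else seq(center + halfwin, center - halfwin)
    pos[pos < lim[1] | pos >= lim[2]] <- NA_integer_
    out <- rep(NA_real_, length(pos))
    ok <- !is.na(pos)
    out[ok] <- track_values(track, chrom, pos[ok])
    out
  }
  skipped <- 0L
  raw_rows <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    row <- win(a$chrom, a$strand, a$gpos, c(a$exon_start, a$exon_end))
    if (all(is.na(row))) { skipped <- skipped + 1L; next }
    raw_rows[[length(raw_rows) + 1L]] <- row
  }
  if (length(raw_rows) == 0L) stop("no PTC anchor with in-exon positions")
  raw <- colMeans(do.call(rbind, raw_rows), na.rm = TRUE)
  nb <- min(n_baseline, nrow(baseline_exons))
  bi <- with_seed(seed, sample.int(nrow(baseline_exons), nb))
  base_rows <- t(vapply(bi, function(k) {
    b <- baseline_exons[k, ]
    center <- as.integer((b$start + b$end) %/% 2L)
    win(b$chrom, b$strand, center, c(b$start, b$end))
  }, numeric(2L * halfwin + 1L)))
  baseline <- colMeans(base_rows, na.rm = TRUE)
  structure(list(label = "ptc", n_anchors = length(raw_rows),
                 n_skipped = skipped, raw = raw, baseline = baseline,
                 mean_score = raw - baseline, baseline_subtracted = TRUE),
            class = "cons_profile")
}

#' Stop-codon identity distribution and Fisher tests
#'
#' Tabulates the frequencies of TAA/TAG/TGA among: the supplied
#' regulated-PTC stop codons, the reference isoforms' annotated stop
#' codons, and seeded random samples of genomic trinucleotides (all
#' three reading frames, random strand) drawn from exonic, intronic
#' and intergenic space as defined by the gene models.  Pairwise 2x3
#' Fisher's exact tests compare the PTC set against the exonic
#' background and against the annotated stops (exact p below
#' `simulate_above` total counts, simulated p above).
#'
#' @param ptc_codons character vector of DNA stop triplets from
#'   regulated PTC+ junctions (pre-filtered by the caller's fold
#'   change / read thresholds).
#' @param models list of [gene_model()] objects.
#' @param genome named [Biostrings::DNAStringSet].
#' @param n_sample genomic trinucleotide sample size per category
#'   (default 1e5 candidate positions).
#' @param seed RNG seed for the genomic sampling.
#' @param simulate_above simulate Fisher p-values when a table's
#'   total exceeds this (default 1000).
#' @return list with `table` (categories x codons counts, RNA codon
#'   labels), `proportions`, and `tests` (named list of `htest`).
#' @export
stop_identity_table <- function(ptc_codons, models, genome,
                                n_sample = 1e5L, seed = 1L,
                                simulate_above = 1000L) {
  stops <- c("TAA", "TAG", "TGA")
  refseq <- character(0)
  for (g in models) {
    iso <- longest_isoform(g, cds_only = TRUE)
    if (is.null(iso)) next
    fs <- find_first_stop(chain_seq(genome, g$chrom, g$strand, iso$exons),
                          iso$cds_start)
    if (!is.na(fs$stop_codon)) refseq <- c(refseq, fs$stop_codon)
  }
  masks <- genome_index(models)
  sample_category <- function(category, off) {
    with_seed(seed + off, {
      found <- character(0)
      for (chrom in names(genome)) {
        cs <- as.character(genome[[chrom]])
        clen <- nchar(cs)
        pos <- sample.int(clen - 3L, min(n_sample, clen - 3L))
        ex <- masks$exons[masks$exons$chrom == chrom, , drop = FALSE]
        sp <- masks$spans[masks$spans$chrom == chrom, , drop = FALSE]
        in_ex <- vapply(pos, function(p) any(ex$start <= p & ex$end > p),
                        logical(1))
        in_sp <- vapply(pos, function(p) any(sp$start <= p & sp$end > p),
                        logical(1))
        keep <- switch(category, exonic = in_ex,
                       intronic = in_sp & !in_ex,
                       intergenic = !in_sp)
        pos <- pos[keep]
        if (length(pos) == 0L) next
        tri <- substring(cs, pos + 1L, pos + 3L)
        flip <- sample(c(TRUE, FALSE), length(tri), replace = TRUE)
        tri[flip] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(tri[flip])))
        found <- c(found, tri[tri %in% stops])
      }
      found
    })
  }
  cats <- list(ptc = ptc_codons[ptc_codons %in% stops],
               refseq_stops = refseq,
               exonic = sample_category("exonic", 1L),
               intronic = sample_category("intronic", 2L),
               intergenic = sample_category("intergenic", 3L))
  empty <- names(cats)[vapply(cats, length, integer(1)) == 0L]
  if (length(empty)) {
    warning("category with zero stops excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
    cats <- cats[setdiff(names(cats), empty)]
  }
  tab <- t(vapply(cats, function(x) table(factor(x, levels = stops)),
                  numeric(3)))
  colnames(tab) <- rna_codon(stops)
  ftest <- function(a, b) {
    m <- tab[c(a, b), , drop = FALSE]
    if (sum(m) > simulate_above)
      with_seed(seed + 9L,
                stats::fisher.test(m, simulate.p.value = TRUE, B = 1e5))
    else stats::fisher.test(m)
  }
  tests <- list()
  if (all(c("ptc", "exonic") %in% rownames(tab)))
    tests$ptc_vs_exonic <- ftest("ptc", "exonic")
  if (all(c("ptc", "refseq_stops") %in% rownames(tab)))
    tests$ptc_vs_refseq <- ftest("ptc", "refseq_stops")
  list(table = tab, proportions = tab / rowSums(tab), tests = tests)
}

#' PTC+/PTC- junction ratio binned by expression
#'
#' Bins junctions by RPKM in increments of `bin_width` and reports,
#' per bin, the count of PTC+ and PTC- junctions and their ratio (no
#' minimum read cutoff is applied; junctions with `NA` PTC status are
#' excluded).  Bins with no PTC- junction have an undefined (flagged
#' `NA`) ratio.
#'
#' @param is_ptc logical PTC status per junction (`NA` allowed).
#' @param rpkm_values numeric junction RPKM, same order.
#' @param bin_width RPKM bin width (default 1).
#' @return data.frame with `bin_lo`, `bin_hi`, `n_ptc`, `n_nonptc`,
#'   `ratio`.
#' @export
ptc_fraction_by_expression <- function(is_ptc, rpkm_values, bin_width = 1) {
  keep <- !is.na(is_ptc) & !is.na(rpkm_values)
  is_ptc <- is_ptc[keep]; rpkm_values <- rpkm_values[keep]
  bin <- floor(rpkm_values / bin_width)
  lv <- sort(unique(bin))
  n_ptc <- vapply(lv, function(b) sum(is_ptc[bin == b]), numeric(1))
  n_non <- vapply(lv, function(b) sum(!is_ptc[bin == b]), numeric(1))
  data.frame(bin_lo = lv * bin_width, bin_hi = (lv + 1) * bin_width,
             n_ptc = n_ptc, n_nonptc = n_non,
             ratio = ifelse(n_non > 0, n_ptc / n_non, NA_real_))
}
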