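#' Count reads per junction
#'
#' Tallies junction-assigned reads from one sample onto the database:
#' one count per junction, junctions with zero reads retained with
#' count 0, so the counts sum exactly to the number of
#' junction-assigned reads.
#'
#' @param assignments data.frame from [map_reads()] /
#'   [truncate_and_rescue()] / [import_sam()] for one sample.
#' @param db a `junction_db`.
#' @return integer vector of counts, named by `junction_id` and
#'   aligned to `db$junctions`.
#' @export
count_junctions <- function(assignments, db) {
  jr <- assignments$junction_id[assignments$target == "junction"]
  tab <- table(jr)
  counts <- as.integer(tab[db$junctions$junction_id])
  counts[is.na(counts)] <- 0L
  names(counts) <- db$junctions$junction_id
  counts
}

#' Reads per kilobase of feature per million mapped reads
#'
#' `count / (feature_len/1000) / (mapped_reads/1e6)`.  For junctions
#' the feature length is the constant `2 * flank_len`, so junction
#' RPKM ranks identically to depth-normalised counts.
#'
#' @param count read count(s).
#' @param feature_len feature length in nt (> 0).
#' @param mapped_reads mapped library size (> 0).
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(count, feature_len, mapped_reads) {
  if (any(mapped_reads <= 0)) stop("mapped_reads must be positive")
  if (any(feature_len <= 0)) stop("feature_len must be positive")
  count / (feature_len / 1000) / (mapped_reads / 1e6)
}

#' Between-sample normalization factors
#'
#' Returns one multiplicative scale factor per sample (reference =
#' first sample, factor 1): raw counts are multiplied by their
#' sample's factor before fold changes are computed.
#' `"upper_quartile"` equalizes the 75th percentile of nonzero feature
#' counts; `"tmm"` uses the trimmed mean of M-values (via
#' \pkg{edgeR}, 30\% M / 5\% A trim) composed with library size, so a
#' pure 2x depth difference yields a factor of 0.5 for the deeper
#' sample under either method.
#'
#' @param counts numeric matrix, features x samples (>= 2 columns).
#' @param method `"upper_quartile"`, `"tmm"`, or `"none"`.
#' @return named numeric vector of per-sample factors.
#' @export
normalization_factors <- function(counts,
                                  method = c("upper_quartile", "tmm",
                                             "none")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (any(colSums(counts) == 0)) stop("all-zero sample in counts")
  f <- switch(method,
    none = rep(1, ncol(counts)),
    upper_quartile = {
      uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0], 0.75,
                                                         names = FALSE))
      uq[1] / uq
    },
    tmm = {
      nf <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = 1L)
      eff <- colSums(counts) * nf
      eff[1] / eff
    })
  names(f) <- colnames(counts)
  f
}

#' Classify junction regulation between two conditions
#'
#' Junctions with fewer than `min_reads` raw reads in both samples are
#' `below_cutoff`; otherwise the KO/WT fold change is computed on
#' normalized counts with a pseudocount, and junctions at least 2-fold
#' up (down) in KO are `upregulated` (`downregulated`), the rest
#' `unregulated`.
#'
#' @param wt,ko integer raw counts per junction (same order).
#' @param factor_wt,factor_ko normalization factors applied to each
#'   sample's raw counts.
#' @param min_reads minimum reads in WT *or* KO (default 3).
#' @param fold_cut fold-change threshold (default 2).
#' @param pseudocount added to both normalized counts (default 0.5),
#'   so junctions absent from one sample still get a finite fold.
#' @return data.frame with `status` (factor: upregulated,
#'   downregulated, unregulated, below_cutoff) and `fold_change`.
#' @export
call_regulation <- function(wt, ko, factor_wt = 1, factor_ko = 1,
                            min_reads = 3L, fold_cut = 2,
                            pseudocount = 0.5) {
  fc <- (ko * factor_ko + pseudocount) / (wt * factor_wt + pseudocount)
  status <- rep("unregulated", length(wt))
  status[fc >= fold_cut] <- "upregulated"
  status[fc <= 1 / fold_cut] <- "downregulated"
  status[pmax(wt, ko) < min_reads] <- "below_cutoff"
  data.frame(status = factor(status, levels = c("upregulated",
                                                "downregulated",
                                                "unregulated",
                                                "below_cutoff")),
             fold_change = fc)
}

#' Gene-level expression (counts and RPKM)
#'
#' Counts reads overlapping each gene model (exonic, intronic and
#' junction assignments carrying the gene id) and computes RPKM using
#' the union-exon model length: overlapping union exons are merged
#' before summing, gene length is taken in kb and the mapped library
#' size in millions.
#'
#' @param assignments per-sample assignment data.frame.
#' @param models list of [gene_model()] objects.
#' @param mapped_reads mapped library size; defaults to the number of
#'   non-unmapped assignments.
#' @return data.frame with `gene_id`, `count`, `length`, `rpkm`.
#' @export
gene_expression <- function(assignments, models, mapped_reads = NULL) {
  if (is.null(mapped_reads))
    mapped_reads <- sum(assignments$target != "unmapped")
  counted <- assignments$target %in% c("genome_exonic", "genome_intronic",
                                       "junction")
  tab <- table(assignments$gene_id[counted])
  gl <- vapply(models, function(g) {
    r <- IRanges::reduce(IRanges::IRanges(start = g$exon_union$start + 1L,
                                          end = g$exon_union$end))
    sum(IRanges::width(r))
  }, numeric(1))
  cnt <- as.integer(tab[names(models)])
  cnt[is.na(cnt)] <- 0L
  data.frame(gene_id = names(models), count = cnt, length = gl,
             rpkm = rpkm(cnt, gl, mapped_reads), row.names = NULL)
}
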