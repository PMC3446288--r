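#' Splice one junction into a reference isoform
#'
#' Builds the transcript that results from using junction `j` in the
#' context of the backbone isoform `ref`: all exonic sequence between
#' the junction's donor and acceptor is removed, the two flanking
#' exons are clipped to the junction's boundaries, and reference exons
#' wholly inside the spliced-out interval are dropped.  When the
#' junction's donor or acceptor exon is not part of `ref` (a novel,
#' poison, or alternative-boundary exon), that exon is taken from the
#' gene's exon union and the chain continues with the reference exons
#' downstream (upstream) of it -- the novel-exon splice-through
#' policy.
#'
#' The reference CDS start is carried over by mapping the genomic
#' position of the start codon into the new chain; it becomes `NA`
#' (flagged) when the junction removes it.
#'
#' @param gene a [gene_model()].
#' @param ref backbone isoform of `gene` (see [longest_isoform()]).
#' @param j one junction: a list or one-row data.frame with `donor`,
#'   `acceptor` (genomic boundary coordinates) and optionally
#'   `donor_exon`, `acceptor_exon` (row indices into
#'   `gene$exon_union`).
#' @param genome named [Biostrings::DNAStringSet].
#' @return a `spliced_transcript`: list with `exon_chain` (genomic
#'   0-based half-open intervals in transcription order), `seq`,
#'   `junction_offsets` (transcript-relative boundary positions),
#'   `cds_start`, and `flags`.
#' @export
splice_in_junction <- function(gene, ref, j, genome) {
  strand <- gene$strand
  d <- txc(j$donor, strand)
  a <- txc(j$acceptor, strand)
  tex <- txc_exons(ref$exons, strand)
  nr <- nrow(tex)
  if (a <= tex$s[1] || d > tex$e[nr])
    stop("junction outside reference isoform '", ref$id, "'")
  uni <- txc_exons(gene$exon_union, strand)
  flags <- character(0)

  # --- upstream side
  keep_up <- which(tex$e <= d)
  inside_up <- which(tex$s < d & tex$e > d)
  if (length(inside_up)) {                       # donor inside a ref exon
    up <- rbind(tex[keep_up, , drop = FALSE],
                data.frame(s = tex$s[inside_up[1]], e = d))
  } else if (length(keep_up) && tex$e[max(keep_up)] == d) {
    up <- tex[keep_up, , drop = FALSE]           # donor on a ref boundary
  } else {
    de <- resolve_exon(uni, j, "donor", d, strand)
    if (is.na(de)) stop("donor boundary ", j$donor,
                        " matches no exon of gene '", gene$gene_id, "'")
    keep_up <- which(tex$e <= uni$s[de])
    up <- rbind(tex[keep_up, , drop = FALSE],
                data.frame(s = uni$s[de], e = d))
    flags <- c(flags, "novel_donor_exon")
  }
  if (nrow(up) == 0L) stop("junction outside reference isoform '",
                           ref$id, "'")

  # --- downstream side
  inside_dn <- which(tex$s <= a & tex$e > a)
  if (length(inside_dn)) {
    i <- inside_dn[1]
    dn <- rbind(data.frame(s = a, e = tex$e[i]),
                tex[tex$s >= tex$e[i], , drop = FALSE])
  } else {
    ae <- resolve_exon(uni, j, "acceptor", a, strand)
    if (is.na(ae)) stop("acceptor boundary ", j$acceptor,
                        " matches no exon of gene '", gene$gene_id, "'")
    dn <- rbind(data.frame(s = a, e = uni$e[ae]),
                tex[tex$s >= uni$e[ae], , drop = FALSE])
    flags <- c(flags, "novel_acceptor_exon")
  }

  chain_tx <- rbind(up, dn)
  gx <- t(vapply(seq_len(nrow(chain_tx)), function(i)
    gen_interval(chain_tx$s[i], chain_tx$e[i], strand), numeric(2)))
  chain <- data.frame(start = as.integer(gx[, 1]), end = as.integer(gx[, 2]))
  lens <- chain$end - chain$start
  offs <- cumsum(lens)
  junction_offsets <- offs[-length(offs)]
  seq <- chain_seq(genome, gene$chrom, strand, chain)

  cds_start <- NA_integer_
  if (!is.na(ref$cds_start)) {
    g_cds <- tx_to_genomic(ref$exons, strand, ref$cds_start)
    cds_start <- genomic_to_tx(chain, strand, g_cds)
    if (is.na(cds_start)) flags <- c(flags, "cds_start_lost")
  } else flags <- c(flags, "no_cds")
  structure(list(exon_chain = chain, seq = seq,
                 junction_offsets = junction_offsets,
                 cds_start = cds_start, flags = flags),
            class = "spliced_transcript")
}

# Find the exon-union row whose boundary matches a junction endpoint;
# prefer the explicitly referenced exon, fall back to boundary match
# (ties broken toward the longest variant).
resolve_exon <- function(uni_tx, j, side, boundary, strand) {
  ref_field <- paste0(side, "_exon")
  if (!is.null(j[[ref_field]]) && length(j[[ref_field]]) == 1L &&
      !is.na(j[[ref_field]]))
    return(as.integer(j[[ref_field]]))
  cand <- if (side == "donor") which(uni_tx$e == boundary)
          else which(uni_tx$s == boundary)
  if (length(cand) == 0L) return(NA_integer_)
  cand[order(-(uni_tx$e[cand] - uni_tx$s[cand]))][1]
}

#' Find the first in-frame stop codon
#'
#' Scans in-frame triplets of `seq` from `cds_start` and returns the
#' transcript offset and identity of the first stop (`TAA`/`TAG`/
#' `TGA` on the sense strand), or `NA`s if none occurs before the
#' transcript end.
#'
#' @param seq character transcript sequence (DNA alphabet).
#' @param cds_start 0-based offset of the start codon.
#' @return list with `stop_pos` (0-based offset of the stop's first
#'   base) and `stop_codon` (DNA triplet or `NA`).
#' @export
find_first_stop <- function(seq, cds_start) {
  n <- nchar(seq)
  if (is.na(cds_start) || n < cds_start + 3L)
    return(list(stop_pos = NA_integer_, stop_codon = NA_character_))
  starts <- seq.int(cds_start + 1L, n - 2L, by = 3L)
  cods <- substring(seq, starts, starts + 2L)
  hit <- which(cods %in% c("TAA", "TAG", "TGA"))
  if (length(hit) == 0L)
    return(list(stop_pos = NA_integer_, stop_codon = NA_character_))
  list(stop_pos = starts[hit[1]] - 1L, stop_codon = cods[hit[1]])
}

#' Predict PTC status of one junction under the 50-nt rule
#'
#' Splices the junction into the backbone isoform, locates the first
#' in-frame stop codon, and measures the distance from the stop's 3'
#' end to the transcript's last exon-exon boundary.  The junction is
#' PTC+ when that distance is at least `ptc_min_dist` (inclusive, per
#' the 50-nucleotide rule) *and* the stop is not the reference
#' isoform's own annotated stop.  Stops in the last exon are at
#' non-positive distance and therefore never PTC; transcripts with no
#' stop are flagged and called PTC-.
#'
#' @inheritParams splice_in_junction
#' @param ptc_min_dist minimum stop-to-last-junction distance in nt
#'   (default 50).
#' @param ref_stop_gpos optional precomputed genomic position of the
#'   reference isoform's own stop codon (first base); computed on the
#'   fly when missing.
#' @return one-row data.frame: `is_ptc`, `stop_pos`, `stop_codon`
#'   (DNA; see [rna_codon()] for report form), `dist_to_last_junction`
#'   (negative when the stop lies downstream of the last boundary),
#'   `stop_chrom`, `stop_gpos` (genomic 0-based position of the
#'   stop's first base), `stop_exon_start`/`stop_exon_end` (bounds of
#'   the chain exon holding it), `flags`.
#' @export
call_ptc <- function(gene, ref, j, genome, ptc_min_dist = 50L,
                     ref_stop_gpos = NULL) {
  st <- splice_in_junction(gene, ref, j, genome)
  flags <- st$flags
  na_row <- function(flags) data.frame(
    is_ptc = NA, stop_pos = NA_integer_, stop_codon = NA_character_,
    dist_to_last_junction = NA_integer_, stop_chrom = NA_character_,
    stop_gpos = NA_integer_, stop_exon_start = NA_integer_,
    stop_exon_end = NA_integer_, flags = paste(flags, collapse = ","))
  if (is.na(st$cds_start)) return(na_row(flags))
  fs <- find_first_stop(st$seq, st$cds_start)
  if (is.na(fs$stop_pos)) {
    out <- na_row(c(flags, "no_stop_found"))
    out$is_ptc <- FALSE
    return(out)
  }
  dist <- if (length(st$junction_offsets))
    max(st$junction_offsets) - (fs$stop_pos + 3L) else NA_integer_
  gpos <- tx_to_genomic(st$exon_chain, gene$strand, fs$stop_pos)
  lens <- st$exon_chain$end - st$exon_chain$start
  cum <- c(0L, cumsum(lens))
  ei <- findInterval(fs$stop_pos, cum, rightmost.closed = FALSE)
  annotated <- FALSE
  if (is.null(ref_stop_gpos)) ref_stop_gpos <- ref_stop_position(gene, ref,
                                                                 genome)
  if (!is.na(ref_stop_gpos)) annotated <- identical(ref_stop_gpos, gpos)
  if (annotated) flags <- c(flags, "annotated_stop")
  is_ptc <- !is.na(dist) && dist >= ptc_min_dist && !annotated
  data.frame(is_ptc = is_ptc, stop_pos = fs$stop_pos,
             stop_codon = fs$stop_codon,
             dist_to_last_junction = dist,
             stop_chrom = gene$chrom, stop_gpos = gpos,
             stop_exon_start = st$exon_chain$start[ei],
             stop_exon_end = st$exon_chain$end[ei],
             flags = paste(flags, collapse = ","))
}

# genomic position (first base) of the reference isoform's own stop
ref_stop_position <- function(gene, ref, genome) {
  if (is.na(ref$cds_start)) return(NA_integer_)
  rs <- find_first_stop(chain_seq(genome, gene$chrom, gene$strand,
                                  ref$exons), ref$cds_start)
  if (is.na(rs$stop_pos)) return(NA_integer_)
  tx_to_genomic(ref$exons, gene$strand, rs$stop_pos)
}

#' PTC calls for every junction in the database
#'
#' Applies [call_ptc()] junction-by-junction against each gene's
#' backbone (the longest CDS-bearing isoform).  Junctions of
#' non-coding genes, junctions falling outside the backbone, and
#' junctions with an unresolvable frame get `is_ptc = NA` and are
#' excluded from PTC+/PTC- denominators downstream.
#'
#' @param db a `junction_db`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param ptc_min_dist see [call_ptc()].
#' @return data.frame aligned to `db$junctions` with the [call_ptc()]
#'   columns plus `junction_id`.
#' @export
ptc_table <- function(db, genome, ptc_min_dist = 50L) {
  genome <- genome_chars(genome)
  backbones <- lapply(db$models, longest_isoform, cds_only = TRUE)
  ref_stops <- lapply(names(db$models), function(gid) {
    if (is.null(backbones[[gid]])) return(NA_integer_)
    ref_stop_position(db$models[[gid]], backbones[[gid]], genome)
  })
  names(ref_stops) <- names(db$models)
  rows <- lapply(seq_len(nrow(db$junctions)), function(i) {
    j <- db$junctions[i, ]
    g <- db$models[[j$gene_id]]
    base <- data.frame(junction_id = j$junction_id)
    if (is.null(g) || is.null(backbones[[j$gene_id]])) {
      call <- data.frame(is_ptc = NA, stop_pos = NA_integer_,
                         stop_codon = NA_character_,
                         dist_to_last_junction = NA_integer_,
                         stop_chrom = NA_character_, stop_gpos = NA_integer_,
                         stop_exon_start = NA_integer_,
                         stop_exon_end = NA_integer_, flags = "no_backbone")
    } else {
      call <- tryCatch(call_ptc(g, backbones[[j$gene_id]], j, genome,
                                ptc_min_dist,
                                ref_stop_gpos = ref_stops[[j$gene_id]]),
                       error = function(e) data.frame(
                         is_ptc = NA, stop_pos = NA_integer_,
                         stop_codon = NA_character_,
                         dist_to_last_junction = NA_integer_,
                         stop_chrom = NA_character_,
                         stop_gpos = NA_integer_,
                         stop_exon_start = NA_integer_,
                         stop_exon_end = NA_integer_,
                         flags = "outside_reference"))
    }
    cbind(base, call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label an event's inclusion/exclusion PTC semantics
#'
#' An event is `ptc_on_inclusion` when some junction defining the
#' inclusion path is PTC+ while the exclusion path is PTC-,
#' `ptc_on_exclusion` for the converse, `ptc_free` when neither path
#' is PTC+, and `both_ptc` (outside the field's usual taxonomy,
#' flagged) when both are.  ALE events are labelled `NA`: with two
#' alternative last exons the 50-nt rule has no meaningful reference
#' boundary.
#'
#' @param event a splice event from [classify_events()].
#' @param calls the [ptc_table()] data.frame.
#' @return character scalar or `NA`.
#' @export
classify_inclusion_exclusion <- function(event, calls) {
  if (event$cls == "ALE") return(NA_character_)
  side <- function(ids) {
    v <- calls$is_ptc[match(ids, calls$junction_id)]
    if (all(is.na(v))) NA else any(v, na.rm = TRUE)
  }
  inc <- side(event$inclusion)
  exc <- side(event$exclusion)
  if (is.na(inc) || is.na(exc)) return(NA_character_)
  if (inc && exc) return("both_ptc")
  if (inc) return("ptc_on_inclusion")
  if (exc) return("ptc_on_exclusion")
  "ptc_free"
}
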