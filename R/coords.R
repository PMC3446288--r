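# Internal coordinate conventions and small shared helpers.
#
# All genomic intervals in this package are 0-based half-open (BED
# convention): an exon [start, end) has length end - start.  GTF input
# (1-based closed) is converted at the boundary.
#
# "Transcript coordinates" (txc) linearise both strands onto one axis so
# upstream/downstream comparisons are strand-free: on '+' a genomic
# boundary x maps to x, on '-' to -x.  A genomic exon [start, end) maps
# to the txc interval [txc_s, txc_e) with txc_s < txc_e and
# txc_e - txc_s equal to the exon length.

txc <- function(x, strand) ifelse(strand == "+", x, -x)

txc_exons <- function(exons, strand) {
  if (strand == "+") {
    data.frame(s = exons$start, e = exons$end)
  } else {
    data.frame(s = -exons$end, e = -exons$start)
  }
}

# Inverse: txc interval back to genomic [start, end)
gen_interval <- function(s, e, strand) {
  if (strand == "+") c(s, e) else c(-e, -s)
}

#' Extract the strand-corrected sequence of one exon
#'
#' @param genome a named [Biostrings::DNAStringSet] of chromosomes, or
#'   a named list/vector of plain character chromosome strings (see
#'   [genome_chars()]) for hot loops.
#' @param chrom,strand,start,end exon location, 0-based half-open.
#' @return character scalar, transcript-strand orientation.
#' @keywords internal
exon_seq <- function(genome, chrom, strand, start, end) {
  if (is.character(genome) || is.list(genome)) {
    s <- substr(genome[[chrom]], start + 1L, end)
    if (strand == "-")
      s <- intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
    return(s)
  }
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# one-off conversion of a DNAStringSet genome to plain character
# strings, for repeated substring extraction
genome_chars <- function(genome) {
  if (is.character(genome) || is.list(genome)) return(genome)
  stats::setNames(as.list(as.character(genome)), names(genome))
}

# Spliced sequence of an exon chain given in transcription order.
chain_seq <- function(genome, chrom, strand, exons) {
  paste(vapply(seq_len(nrow(exons)), function(i) {
    exon_seq(genome, chrom, strand, exons$start[i], exons$end[i])
  }, character(1)), collapse = "")
}

# Map a transcript offset (0-based) to the genomic coordinate of that
# base, through an exon chain in transcription order.
tx_to_genomic <- function(exons, strand, offset) {
  lens <- exons$end - exons$start
  cum <- cumsum(lens)
  i <- which(offset < cum)[1]
  if (is.na(i)) return(NA_integer_)
  within <- offset - c(0L, cum)[i]
  if (strand == "+") exons$start[i] + within else exons$end[i] - 1L - within
}

# Map a genomic base coordinate to a transcript offset (0-based), or NA
# when the base is not exonic in the chain.
genomic_to_tx <- function(exons, strand, pos) {
  lens <- exons$end - exons$start
  cum <- c(0L, cumsum(lens))
  for (i in seq_len(nrow(exons))) {
    if (pos >= exons$start[i] && pos < exons$end[i]) {
      within <- if (strand == "+") pos - exons$start[i] else exons$end[i] - 1L - pos
      return(cum[i] + within)
    }
  }
  NA_integer_
}

# Deterministic per-call RNG scope: evaluates expr under a fixed seed
# without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' RNA rendering of a DNA codon for report output
#'
#' @param x character vector of DNA triplets (e.g. `"TGA"`).
#' @return the same triplets in the RNA alphabet (`"UGA"`).
#' @export
rna_codon <- function(x) chartr("Tt", "Uu", x)
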