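#' Configuration for the synthetic NMD study generator
#'
#' Defines the conditions of a simulated two-condition (WT vs
#' NMD-deficient KO) experiment: a synthetic genome of designed
#' multi-exon genes, each carrying one alternative-splicing event of a
#' chosen class with chosen PTC semantics, and single-end read sets in
#' which the KO stabilizes PTC+ isoforms.
#'
#' Designed exonic sequence is drawn from the {A, C, G} alphabet, so
#' stop codons exist exactly where the generator plants them (start
#' codons, annotated stops, poison/frameshift stops); introns and
#' intergenic space use all four bases.  Every designed junction's PTC
#' status is re-verified through [call_ptc()] before the simulation is
#' emitted.
#'
#' @param n_genes number of genes (one designed event per gene).
#' @param event_mix named integer vector of per-class gene counts
#'   (classes among SES, MES, A5SS, A3SS, MXE, AFE, ALE); by default
#'   `n_genes` is spread over all seven classes.
#' @param ptc_mix named list (per class) of proportions over
#'   `ptc_on_inclusion` / `ptc_on_exclusion` / `ptc_free`.
#' @param exon_len_internal,exon_len_terminal,intron_len length ranges
#'   in nt.
#' @param alt_ext_len extension length of A5SS/A3SS boundary variants
#'   (a multiple of 3).
#' @param read_length single-end read length (default 75 nt).
#' @param depth reads per gene per condition (default 3000, giving
#'   designed junctions tens of spanning reads).
#' @param stabilization_factor multiplier on PTC+ isoform abundance in
#'   the KO before renormalization (default 4).
#' @param alt_fraction WT abundance of the alternative isoform
#'   (default 0.1).
#' @param splice_noise_rate per-gene probability of one random
#'   low-abundance (noise) junction (default 0.2).
#' @param noise_reads expected reads on a noise junction (default 2,
#'   keeping noise junction RPKM in the low-expression range).
#' @param anchor_min junction anchor used for ground-truth spanning
#'   counts (match the mapper's).
#' @param ptc_stop_probs sampling weights of the planted PTC stop
#'   codon identity (default biased toward TGA, emulating the UGA
#'   preference of NMD-eliciting stops); annotated stops are drawn
#'   uniformly.
#' @param intergenic_gap nt between genes.
#' @param extra_exon_max up to this many extra constitutive internal
#'   exons per gene.
#' @param seed master seed; all outputs are byte-identical for a
#'   fixed seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L, event_mix = NULL, ptc_mix = NULL,
                       exon_len_internal = c(90L, 150L),
                       exon_len_terminal = c(150L, 250L),
                       intron_len = c(150L, 300L), alt_ext_len = 45L,
                       read_length = 75L, depth = 3000L,
                       stabilization_factor = 4, alt_fraction = 0.1,
                       splice_noise_rate = 0.2, noise_reads = 2L,
                       anchor_min = 5L, intergenic_gap = 800L,
                       extra_exon_max = 1L,
                       ptc_stop_probs = c(TAA = 0.15, TAG = 0.15,
                                          TGA = 0.70),
                       seed = 1L) {
  classes <- c("SES", "MES", "A5SS", "A3SS", "MXE", "AFE", "ALE")
  if (is.null(event_mix)) {
    probs <- c(SES = 0.28, MES = 0.12, A5SS = 0.12, A3SS = 0.12,
               MXE = 0.12, AFE = 0.12, ALE = 0.12)
    event_mix <- alloc_counts(n_genes, probs)
  }
  if (!all(names(event_mix) %in% classes))
    stop("unknown event class in event_mix: ",
         paste(setdiff(names(event_mix), classes), collapse = ", "))
  if (any(event_mix < 0)) stop("negative event_mix entry")
  n_genes <- sum(event_mix)
  default_ptc <- list(
    SES = c(ptc_on_inclusion = 0.35, ptc_on_exclusion = 0.35,
            ptc_free = 0.30),
    MES = c(ptc_on_exclusion = 0.5, ptc_free = 0.5),
    A5SS = c(ptc_on_inclusion = 0.5, ptc_free = 0.5),
    A3SS = c(ptc_on_inclusion = 0.5, ptc_free = 0.5),
    MXE = c(ptc_on_exclusion = 0.3, ptc_free = 0.7),
    AFE = c(ptc_free = 1), ALE = c(ptc_free = 1))
  if (is.null(ptc_mix)) ptc_mix <- default_ptc
  for (cl in names(ptc_mix)) {
    allowed <- names(default_ptc[[cl]])
    if (!all(names(ptc_mix[[cl]]) %in% allowed))
      stop("unsatisfiable ptc_mix for ", cl, ": allowed kinds are ",
           paste(allowed, collapse = ", "))
  }
  if (stabilization_factor < 1) stop("stabilization_factor must be >= 1")
  if (alt_fraction <= 0 || alt_fraction >= 1)
    stop("alt_fraction must be in (0, 1)")
  if (splice_noise_rate < 0 || splice_noise_rate > 1)
    stop("splice_noise_rate must be in [0, 1]")
  if (alt_ext_len %% 3L != 0L || alt_ext_len < 9L)
    stop("alt_ext_len must be a multiple of 3 and >= 9")
  if (exon_len_internal[1] < 65L)
    stop("internal exons must be >= 65 nt (room for planted stops ",
         "50 nt upstream of a junction)")
  if (intron_len[1] < 80L)
    stop("introns must be >= 80 nt (conservation windows)")
  if (read_length < 2L * anchor_min) stop("read_length too short")
  structure(list(n_genes = n_genes, event_mix = event_mix,
                 ptc_mix = ptc_mix, exon_len_internal = exon_len_internal,
                 exon_len_terminal = exon_len_terminal,
                 intron_len = intron_len, alt_ext_len = as.integer(alt_ext_len),
                 read_length = as.integer(read_length),
                 depth = as.integer(depth),
                 stabilization_factor = stabilization_factor,
                 alt_fraction = alt_fraction,
                 splice_noise_rate = splice_noise_rate,
                 noise_reads = as.integer(noise_reads),
                 anchor_min = as.integer(anchor_min),
                 intergenic_gap = as.integer(intergenic_gap),
                 extra_exon_max = as.integer(extra_exon_max),
                 ptc_stop_probs = ptc_stop_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# largest-remainder integer allocation of n over named proportions
alloc_counts <- function(n, probs) {
  probs <- probs / sum(probs)
  base <- floor(n * probs)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(n * probs - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

rand_seq <- function(n, letters = c("A", "C", "G")) {
  if (n == 0L) return("")
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# overwrite bases at 0-based local position
plant <- function(seq, pos0, what) {
  substr(seq, pos0 + 1L, pos0 + nchar(what)) <- what
  seq
}

# first offset p >= min_off with (cds_before + p) %% 3 == 0
inframe_offset <- function(cds_before, min_off) {
  p0 <- (3L - cds_before %% 3L) %% 3L
  p0 + 3L * max(0L, ceiling((min_off - p0) / 3))
}

rint <- function(rng) if (rng[1] >= rng[2]) rng[1] else
  sample(seq.int(rng[1], rng[2]), 1L)

# internal exon length with a required length %% 3 residue
rint_mod3 <- function(rng, residue) {
  l <- rint(rng)
  l + ((residue - l) %% 3L)
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Lays out `cfg$n_genes` designed genes (alternating strands) along
#' one synthetic chromosome.  Each gene has a clean CDS-bearing
#' backbone isoform (A) and one alternative isoform (B) realising the
#' designed event; for PTC-bearing designs, isoform B's unique
#' junctions create a stop codon satisfying the 50-nt rule by
#' construction (poison exons carry an in-frame stop; frame-shifting
#' skips expose an out-of-frame stop in the next exon), and isoform B
#' is annotated without CDS records so the backbone remains the clean
#' isoform.  All designed junction PTC statuses are re-verified with
#' [call_ptc()] before the object is returned.
#'
#' @param cfg a [sim_config()].
#' @return a `splice_sim`: list with `cfg`, `genome`
#'   ([Biostrings::DNAStringSet]), `models` (list of [gene_model()]),
#'   and `truth` (per-gene, per-junction, per-isoform and per-event
#'   ground truth tables).
#' @export
simulate_genome_and_models <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, simulate_genome_impl(cfg))
}

simulate_genome_impl <- function(cfg) {
  chrom <- "chrS"
  chrom_seq <- character(0)
  offset <- 0L
  models <- list()
  genes_rows <- list()
  junc_rows <- list()
  iso_truth <- list()
  event_rows <- list()
  classes <- rep(names(cfg$event_mix), cfg$event_mix)
  ptc_of <- unlist(lapply(names(cfg$event_mix), function(cl) {
    k <- cfg$event_mix[[cl]]
    if (k == 0L) return(character(0))
    rep(names(cfg$ptc_mix[[cl]]), alloc_counts(k, cfg$ptc_mix[[cl]]))
  }))
  spanpos <- cfg$read_length - 2L * cfg$anchor_min + 1L
  for (gi in seq_along(classes)) {
    cl <- classes[gi]
    ptc_cl <- ptc_of[gi]
    strand <- if (gi %% 2L == 1L) "+" else "-"
    gid <- sprintf("g%03d", gi)
    d <- design_gene(cl, ptc_cl, cfg)
    gap <- rand_seq(cfg$intergenic_gap, c("A", "C", "G", "T"))
    # place: '-' strand genes store the reverse complement genomically
    local_seq <- d$seq
    if (strand == "-")
      local_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(local_seq)))
    g0 <- offset + cfg$intergenic_gap
    to_genomic <- function(iv) {   # local [s,e) -> genomic [start,end)
      if (strand == "+") c(g0 + iv[1], g0 + iv[2])
      else c(g0 + d$len - iv[2], g0 + d$len - iv[1])
    }
    exons_g <- lapply(d$exons, to_genomic)
    mk_chain <- function(names) {
      df <- do.call(rbind, lapply(names, function(nm)
        data.frame(start = as.integer(exons_g[[nm]][1]),
                   end = as.integer(exons_g[[nm]][2]))))
      rownames(df) <- NULL
      df
    }
    isoA <- isoform(paste0(gid, "_A"), mk_chain(d$isoA),
                    cds_start = d$cds_start, cds_end = d$cds_end)
    isoB <- isoform(paste0(gid, "_B"), mk_chain(d$isoB))
    g <- gene_model(gid, chrom, strand,
                    stats::setNames(list(isoA, isoB),
                                    c(isoA$id, isoB$id)),
                    sources = "synthetic")
    models[[gid]] <- g
    chrom_seq <- c(chrom_seq, gap, local_seq)
    offset <- g0 + d$len
    # ---- junction ground truth
    jkey <- function(exon_names) {   # canonical junction ids of a chain
      ivs <- lapply(exon_names, function(nm) exons_g[[nm]])
      vapply(seq_len(length(ivs) - 1L), function(i) {
        up <- ivs[[i]]; dn <- ivs[[i + 1L]]
        if (strand == "+")
          paste(gid, chrom, strand, up[2], dn[1], sep = "|")
        else paste(gid, chrom, strand, up[1], dn[2], sep = "|")
      }, character(1))
    }
    jA <- jkey(d$isoA); jB <- jkey(d$isoB)
    aw <- c(A = 1 - cfg$alt_fraction, B = cfg$alt_fraction)
    b_is_ptc <- ptc_cl != "ptc_free"
    ak <- if (b_is_ptc) {
      s <- cfg$stabilization_factor
      c(A = aw[["A"]] / (aw[["A"]] + aw[["B"]] * s),
        B = aw[["B"]] * s / (aw[["A"]] + aw[["B"]] * s))
    } else aw
    lens <- c(A = isoform_length(isoA), B = isoform_length(isoB))
    w_wt <- sum(aw * (lens - cfg$read_length + 1L))
    w_ko <- sum(ak * (lens - cfg$read_length + 1L))
    juncs <- unique(c(jA, jB))
    for (id in juncs) {
      inA <- id %in% jA; inB <- id %in% jB
      role <- if (inA && inB) "constitutive"
              else if (inA) "ref_unique" else "alt_unique"
      junc_rows[[length(junc_rows) + 1L]] <- data.frame(
        junction_id = id, gene_id = gid, role = role,
        is_ptc = (role == "alt_unique") && b_is_ptc,
        expected_wt = cfg$depth * spanpos *
          (aw[["A"]] * inA + aw[["B"]] * inB) / w_wt,
        expected_ko = cfg$depth * spanpos *
          (ak[["A"]] * inA + ak[["B"]] * inB) / w_ko)
    }
    # ---- noise junction: a random combinatorial junction not used by
    # either isoform, at low abundance
    noise_id <- NA_character_
    if (stats::runif(1) < cfg$splice_noise_rate) {
      uni <- g$exon_union
      tex <- txc_exons(uni, strand)
      cand <- list()
      for (u in seq_len(nrow(uni) - 1L)) for (v in seq(u + 1L, nrow(uni)))
        if (tex$e[u] <= tex$s[v]) {
          id <- if (strand == "+")
            paste(gid, chrom, strand, uni$end[u], uni$start[v], sep = "|")
          else paste(gid, chrom, strand, uni$start[u], uni$end[v], sep = "|")
          if (!id %in% juncs) cand[[length(cand) + 1L]] <- id
        }
      if (length(cand))
        noise_id <- cand[[sample.int(length(cand), 1L)]]
    }
    genes_rows[[length(genes_rows) + 1L]] <- data.frame(
      gene_id = gid, class = cl, ptc_class = ptc_cl, strand = strand,
      regulated = b_is_ptc, noise_junction = noise_id,
      cassette_start = if (!is.null(d$cassette))
        exons_g[[d$cassette]][1] else NA_integer_,
      cassette_end = if (!is.null(d$cassette))
        exons_g[[d$cassette]][2] else NA_integer_)
    iso_truth[[gid]] <- list(
      A = list(id = isoA$id, exons = isoA$exons, length = lens[["A"]],
               abund_wt = aw[["A"]], abund_ko = ak[["A"]],
               junction_ids = jA),
      B = list(id = isoB$id, exons = isoB$exons, length = lens[["B"]],
               abund_wt = aw[["B"]], abund_ko = ak[["B"]],
               junction_ids = jB))
    # ---- event ground truth (inclusion side per classify_events()
    # conventions)
    ev <- design_event_truth(cl, ptc_cl, jA, jB, d)
    psi <- function(a) 100 * a[[ev$inc_iso]] / (a[["A"]] + a[["B"]])
    event_rows[[length(event_rows) + 1L]] <- data.frame(
      gene_id = gid, class = cl, ptc_class = ptc_cl,
      inclusion = paste(ev$inclusion, collapse = ","),
      exclusion = paste(ev$exclusion, collapse = ","),
      psi_wt = psi(aw), psi_ko = psi(ak))
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chrom_seq, collapse = ""), chrom))
  empty_or <- function(rows, proto) if (length(rows)) do.call(rbind, rows)
                                    else proto
  truth <- list(
    genes = empty_or(genes_rows, data.frame(
      gene_id = character(), class = character(), ptc_class = character(),
      strand = character(), regulated = logical(),
      noise_junction = character(), cassette_start = integer(),
      cassette_end = integer())),
    junctions = empty_or(junc_rows, data.frame(
      junction_id = character(), gene_id = character(), role = character(),
      is_ptc = logical(), expected_wt = numeric(),
      expected_ko = numeric())),
    isoforms = iso_truth,
    events = empty_or(event_rows, data.frame(
      gene_id = character(), class = character(), ptc_class = character(),
      inclusion = character(), exclusion = character(), psi_wt = numeric(),
      psi_ko = numeric())))
  sim <- structure(list(cfg = cfg, genome = genome, models = models,
                        truth = truth), class = "splice_sim")
  if (length(models)) sim <- verify_sim_ptc(sim)
  sim
}

# Re-verify every designed junction's PTC status with call_ptc() and
# record the stop-codon genomic positions in the truth table.
verify_sim_ptc <- function(sim) {
  gch <- genome_chars(sim$genome)
  tj <- sim$truth$junctions
  tj$stop_gpos <- NA_integer_
  tj$stop_codon <- NA_character_
  tj$stop_exon_start <- NA_integer_
  tj$stop_exon_end <- NA_integer_
  for (i in seq_len(nrow(tj))) {
    g <- sim$models[[tj$gene_id[i]]]
    ref <- longest_isoform(g, cds_only = TRUE)
    f <- strsplit(tj$junction_id[i], "|", fixed = TRUE)[[1]]
    j <- list(donor = as.integer(f[4]), acceptor = as.integer(f[5]))
    call <- call_ptc(g, ref, j, gch)
    if (is.na(call$is_ptc) || call$is_ptc != tj$is_ptc[i])
      stop("designed PTC semantics not reproduced for ",
           tj$junction_id[i], " (designed ", tj$is_ptc[i], ", called ",
           call$is_ptc, ")")
    tj$stop_gpos[i] <- call$stop_gpos
    tj$stop_codon[i] <- call$stop_codon
    tj$stop_exon_start[i] <- call$stop_exon_start
    tj$stop_exon_end[i] <- call$stop_exon_end
  }
  sim$truth$junctions <- tj
  sim
}

# ---------------------------------------------------------------------
# Per-class gene design, in local sense coordinates (0-based).  Returns
# seq, len, exons (named local intervals), isoA/isoB (exon name
# chains), cds_start/cds_end (tx offsets on A), cassette (name or
# NULL).
design_gene <- function(cl, ptc_cl, cfg) {
  IL <- cfg$exon_len_internal; TL <- cfg$exon_len_terminal
  GL <- cfg$intron_len; EXT <- cfg$alt_ext_len
  cursor <- 0L
  segs <- list()
  pieces <- character(0)
  add <- function(name, len, exonic) {
    segs[[name]] <<- c(cursor, cursor + len)
    pieces <<- c(pieces, rand_seq(len, if (exonic) c("A", "C", "G")
                                       else c("A", "C", "G", "T")))
    cursor <<- cursor + len
  }
  ex <- function(name, len) add(name, len, TRUE)
  intr <- function(len = rint(GL)) {
    add(paste0("i", length(segs)), len, FALSE)
  }
  n_extra <- if (cl %in% c("AFE", "ALE")) 0L
             else rint(c(0L, cfg$extra_exon_max))
  extras <- if (n_extra > 0L) paste0("x", seq_len(n_extra)) else character(0)
  add_extras <- function() for (nm in extras) { ex(nm, rint_mod3(IL, 0L)); intr() }
  cassette <- NULL
  switch(cl,
    SES = {
      l3 <- if (ptc_cl == "ptc_on_exclusion") rint_mod3(IL, 1L)
            else rint_mod3(IL, 0L)
      ex("e1", rint(TL)); intr()
      ex("e2", rint_mod3(IL, 0L)); intr()
      ex("e3", l3); intr()
      ex("e4", rint_mod3(IL, 0L)); intr()
      add_extras()
      ex("e5", rint(TL))
      with_cas <- c("e1", "e2", "e3", "e4", extras, "e5")
      skip_cas <- c("e1", "e2", "e4", extras, "e5")
      if (ptc_cl == "ptc_on_inclusion") {   # poison exon: backbone skips
        isoA <- skip_cas; isoB <- with_cas
      } else {                              # backbone carries the cassette
        isoA <- with_cas; isoB <- skip_cas
      }
      cassette <- "e3"
    },
    MES = {
      r <- if (ptc_cl == "ptc_on_exclusion") 1L else 0L
      ex("e1", rint(TL)); intr()
      ex("e2", rint_mod3(IL, 0L)); intr()
      ex("e3", rint_mod3(IL, r)); intr()
      ex("e4", rint_mod3(IL, 0L)); intr()
      ex("e5", rint_mod3(IL, 0L)); intr()
      add_extras()
      ex("e6", rint(TL))
      isoA <- c("e1", "e2", "e3", "e4", "e5", extras, "e6")
      isoB <- c("e1", "e2", "e5", extras, "e6")
    },
    A5SS = {
      ex("e1", rint(TL)); intr()
      ex("e2S", rint_mod3(IL, 0L))
      add("ext", EXT, TRUE)              # contiguous extension of e2S
      intr()
      ex("e3", rint_mod3(IL, 0L)); intr()
      add_extras()
      ex("e4", rint(TL))
      segs[["e2L"]] <- c(segs[["e2S"]][1], segs[["ext"]][2])
      isoA <- c("e1", "e2S", "e3", extras, "e4")
      isoB <- c("e1", "e2L", "e3", extras, "e4")
    },
    A3SS = {
      ex("e1", rint(TL)); intr()
      ex("e2", rint_mod3(IL, 0L)); intr()
      add("ext", EXT, TRUE)
      ex("e3S", rint_mod3(IL, 0L)); intr()
      add_extras()
      ex("e4", rint(TL))
      segs[["e3L"]] <- c(segs[["ext"]][1], segs[["e3S"]][2])
      isoA <- c("e1", "e2", "e3S", extras, "e4")
      isoB <- c("e1", "e2", "e3L", extras, "e4")
    },
    MXE = {
      ex("e1", rint(TL)); intr()
      ex("eJ", rint_mod3(IL, 0L)); intr()
      ex("eK", rint_mod3(IL, 0L)); intr()
      ex("e4", rint_mod3(IL, 0L)); intr()
      add_extras()
      ex("e5", rint(TL))
      isoA <- c("e1", "eJ", "e4", extras, "e5")
      isoB <- c("e1", "eK", "e4", extras, "e5")
    },
    AFE = {
      ex("f1", rint(TL)); intr()
      ex("f2", rint_mod3(IL, 0L)); intr()
      ex("e2", rint_mod3(IL, 0L)); intr()
      ex("e3", rint(TL))
      isoA <- c("f1", "e2", "e3")
      isoB <- c("f2", "e2", "e3")
    },
    ALE = {
      ex("e1", rint(TL)); intr()
      ex("e2", rint_mod3(IL, 0L)); intr()
      ex("L1", rint(TL)); intr()
      ex("L2", rint(TL))
      isoA <- c("e1", "e2", "L1")
      isoB <- c("e1", "e2", "L2")
    })
  seq <- paste(pieces, collapse = "")
  exon_iv <- segs[!startsWith(names(segs), "i")]
  elen <- function(nm) exon_iv[[nm]][2] - exon_iv[[nm]][1]
  # ---- plant the start codon (tx offset 9 of isoform A)
  first <- isoA[1]
  seq <- plant(seq, exon_iv[[first]][1] + 9L, "ATGC")
  cds_start <- 9L
  lensA <- vapply(isoA, elen, numeric(1))
  # ---- annotated stop: in-frame TAA in A's last exon
  cb_last <- sum(lensA[-length(lensA)]) - cds_start
  p_stop <- inframe_offset(cb_last, 30L)
  last <- isoA[length(isoA)]
  seq <- plant(seq, exon_iv[[last]][1] + p_stop,
               sample(c("TAA", "TAG", "TGA"), 1L))
  cds_end <- sum(lensA[-length(lensA)]) + p_stop + 3L
  # ---- class/PTC-specific planted stop on the B path
  lensB <- vapply(isoB, elen, numeric(1))
  cb_before <- function(iso, lens, nm)
    sum(lens[seq_len(match(nm, iso) - 1L)]) - cds_start
  if (ptc_cl != "ptc_free") {
    ptc_codon <- sample(names(cfg$ptc_stop_probs), 1L,
                        prob = cfg$ptc_stop_probs)
    tgt <- switch(cl,
      SES = if (ptc_cl == "ptc_on_inclusion") "e3" else "e4",
      MES = "e5", A5SS = "ext", A3SS = "ext", MXE = "eK")
    if (cl %in% c("A5SS", "A3SS")) {
      host <- if (cl == "A5SS") "e2L" else "e3L"
      cb <- cb_before(isoB, lensB, host) +
        (segs[["ext"]][1] - segs[[host]][1])
      q <- inframe_offset(cb, 3L)
      stopifnot(q + 3L <= EXT)
      seq <- plant(seq, segs[["ext"]][1] + q, ptc_codon)
    } else {
      cb <- cb_before(isoB, lensB, tgt)
      q <- inframe_offset(cb, 9L)
      ti <- match(tgt, isoB)
      mids <- seq_along(isoB)
      mids <- mids[mids > ti & mids < length(isoB)]
      stopifnot(q + 3L + 50L <= elen(tgt) + sum(lensB[mids]))
      seq <- plant(seq, exon_iv[[tgt]][1] + q, ptc_codon)
    }
  }
  list(seq = seq, len = nchar(seq), exons = exon_iv, isoA = isoA,
       isoB = isoB, cds_start = cds_start, cds_end = cds_end,
       cassette = cassette)
}

# Event-level ground truth wiring: which isoform realises the
# "inclusion" side under classify_events() conventions.
design_event_truth <- function(cl, ptc_cl, jA, jB, d) {
  switch(cl,
    SES = if (ptc_cl == "ptc_on_inclusion")
      list(inclusion = jB[2:3], exclusion = jA[2], inc_iso = "B")
    else list(inclusion = jA[2:3], exclusion = jB[2], inc_iso = "A"),
    MES = list(inclusion = jA[2:4], exclusion = jB[2], inc_iso = "A"),
    A5SS = list(inclusion = jB[2], exclusion = jA[2], inc_iso = "B"),
    A3SS = list(inclusion = jB[2], exclusion = jA[2], inc_iso = "B"),
    MXE = list(inclusion = jA[1:2], exclusion = jB[1:2], inc_iso = "A"),
    AFE = list(inclusion = jB[1], exclusion = jA[1], inc_iso = "B"),
    ALE = list(inclusion = jA[length(jA)], exclusion = jB[length(jB)],
               inc_iso = "A"))
}

#' Simulate WT and KO read sets with per-read provenance
#'
#' Draws error-free single-end reads of `cfg$read_length` nt with
#' uniform start positions along each isoform, the number of reads per
#' isoform proportional to abundance times effective positions; in the
#' KO, PTC+ isoform abundances are multiplied by the stabilization
#' factor and renormalized (already recorded in the simulation's
#' ground truth).  Genes drawn for splice noise contribute a few reads
#' spanning one random unannotated junction.  Provenance records the
#' true isoform, start position, and the junctions each read spans
#' with the ground-truth anchor.
#'
#' @param sim a `splice_sim` from [simulate_genome_and_models()].
#' @return list with elements `WT` and `KO`, each a list of `reads`
#'   (named [Biostrings::DNAStringSet]) and `provenance` (data.frame:
#'   `read_id`, `gene_id`, `isoform`, `start`, `junctions`).
#' @export
simulate_reads <- function(sim) {
  cfg <- sim$cfg
  out <- list()
  for (cond in c("WT", "KO")) {
    off <- if (cond == "WT") 101L else 102L
    out[[cond]] <- with_seed(cfg$seed + off,
                             simulate_reads_cond(sim, cond))
  }
  out
}

simulate_reads_cond <- function(sim, cond) {
  cfg <- sim$cfg
  gch <- genome_chars(sim$genome)
  rl <- cfg$read_length
  seqs <- character(0)
  ids <- character(0)
  prov <- list()
  for (gid in names(sim$models)) {
    it <- sim$truth$isoforms[[gid]]
    g <- sim$models[[gid]]
    afield <- if (cond == "WT") "abund_wt" else "abund_ko"
    w <- vapply(it, function(x) x[[afield]] * (x$length - rl + 1L),
                numeric(1))
    if (all(w <= 0)) next
    n_iso <- stats::rmultinom(1L, cfg$depth, w)[, 1]
    for (k in seq_along(it)) {
      ni <- n_iso[k]
      if (ni == 0L) next
      iso <- it[[k]]
      iso_seq <- chain_seq(gch, g$chrom, g$strand, iso$exons)
      offs <- cumsum(iso$exons$end - iso$exons$start)
      joffs <- offs[-length(offs)]
      starts <- sample.int(iso$length - rl + 1L, ni, replace = TRUE) - 1L
      rseqs <- substring(iso_seq, starts + 1L, starts + rl)
      rids <- sprintf("%s|%s|%s|%05d", cond, gid, names(it)[k],
                      seq_len(ni))
      spans <- vapply(starts, function(s) {
        hit <- joffs - s >= cfg$anchor_min &
          (s + rl) - joffs >= cfg$anchor_min
        paste(iso$junction_ids[hit], collapse = ",")
      }, character(1))
      seqs <- c(seqs, rseqs)
      ids <- c(ids, rids)
      prov[[length(prov) + 1L]] <- data.frame(
        read_id = rids, gene_id = gid, isoform = names(it)[k],
        start = starts, junctions = spans)
    }
    # noise reads over the gene's designated noise junction
    nj <- sim$truth$genes$noise_junction[sim$truth$genes$gene_id == gid]
    if (!is.na(nj)) {
      nn <- stats::rpois(1L, cfg$noise_reads)
      if (nn > 0L) {
        f <- strsplit(nj, "|", fixed = TRUE)[[1]]
        donor <- as.integer(f[4]); acceptor <- as.integer(f[5])
        uni <- g$exon_union
        tex <- txc_exons(uni, g$strand)
        du <- which(tex$e == txc(donor, g$strand))[1]
        au <- which(tex$s == txc(acceptor, g$strand))[1]
        useq <- exon_seq(gch, g$chrom, g$strand, uni$start[du],
                         uni$end[du])
        dseq <- exon_seq(gch, g$chrom, g$strand, uni$start[au],
                         uni$end[au])
        window <- paste0(substring(useq, max(1L, nchar(useq) - rl + 1L)),
                         substring(dseq, 1L, rl))
        fu <- min(nchar(useq), rl)
        # keep <= rl - anchor_min bases on either side of the boundary
        # so the read fits the junction-index window
        o_min <- max(1L, fu - (rl - cfg$anchor_min) + 1L)
        o_max <- min(fu - cfg$anchor_min + 1L, nchar(window) - rl + 1L)
        if (o_max >= o_min) {
          o <- sample(seq.int(o_min, o_max), nn, replace = TRUE)
          rseqs <- substring(window, o, o + rl - 1L)
          rids <- sprintf("%s|%s|noise|%05d", cond, gid, seq_len(nn))
          seqs <- c(seqs, rseqs)
          ids <- c(ids, rids)
          prov[[length(prov) + 1L]] <- data.frame(
            read_id = rids, gene_id = gid, isoform = "noise",
            start = o - 1L, junctions = nj)
        }
      }
    }
  }
  reads <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  list(reads = reads,
       provenance = if (length(prov)) do.call(rbind, prov)
                    else data.frame(read_id = character(),
                                    gene_id = character(),
                                    isoform = character(),
                                    start = integer(),
                                    junctions = character()))
}

#' Simulate a conservation track with planted signal
#'
#' Produces a per-base track at a constant baseline, with elevated
#' scores planted in the `flank` nt of intron adjacent to each side of
#' every regulated (PTC-bearing) cassette exon, and around every
#' designed PTC stop codon -- giving the skipped-exon and PTC
#' meta-profile analyses a known truth to recover.
#'
#' @param sim a `splice_sim`.
#' @param base baseline score (default 0.35).
#' @param intron_signal planted intronic score around regulated
#'   cassettes (default 0.9).
#' @param ptc_signal planted score around PTC positions (default
#'   0.85).
#' @param flank intronic window width (default 75 nt).
#' @param ptc_halfwin half-window around the PTC (default 10 nt).
#' @return a `cons_track`.
#' @export
simulate_conservation_track <- function(sim, base = 0.35,
                                        intron_signal = 0.9,
                                        ptc_signal = 0.85, flank = 75L,
                                        ptc_halfwin = 10L) {
  v <- rep(base, length(sim$genome[[1]]))
  tg <- sim$truth$genes
  reg <- tg[tg$class == "SES" & tg$regulated, , drop = FALSE]
  for (i in seq_len(nrow(reg))) {
    cs <- reg$cassette_start[i]; ce <- reg$cassette_end[i]
    lo <- max(1L, cs - flank + 1L)
    v[lo:cs] <- intron_signal                   # intron 5' of cassette
    hi <- min(length(v), ce + flank)
    v[(ce + 1L):hi] <- intron_signal            # intron 3' of cassette
  }
  tj <- sim$truth$junctions
  ptc <- tj[tj$is_ptc & !is.na(tj$stop_gpos), , drop = FALSE]
  for (p in ptc$stop_gpos) {
    lo <- max(1L, p + 1L - ptc_halfwin)
    hi <- min(length(v), p + 1L + ptc_halfwin)
    v[lo:hi] <- ptc_signal
  }
  structure(stats::setNames(list(v), names(sim$genome)),
            class = "cons_track")
}

#' Write simulation outputs to disk
#'
#' Emits the genome FASTA, annotation GTF, WT/KO FASTQ files,
#' ground-truth TSVs and (optionally) the conservation WIG into a
#' directory.
#'
#' @param sim a `splice_sim`.
#' @param dir output directory (created if needed).
#' @param reads optional result of [simulate_reads()].
#' @param track optional result of [simulate_conservation_track()].
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, reads = NULL, track = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_gtf(sim$models, file.path(dir, "models.gtf"))
  utils::write.table(sim$truth$junctions,
                     file.path(dir, "truth_junctions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, file.path(dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(reads)) {
    write_fastq(reads$WT$reads, file.path(dir, "reads_WT.fastq"))
    write_fastq(reads$KO$reads, file.path(dir, "reads_KO.fastq"))
  }
  if (!is.null(track))
    write_conservation_track(track, file.path(dir, "conservation.wig"))
  invisible(dir)
}

#' Write reads as FASTQ (uniform high quality)
#'
#' @param reads named [Biostrings::DNAStringSet].
#' @param path output FASTQ.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}
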