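#' Run the full junction/PTC/event analysis end to end
#'
#' Orchestrates the stages in order: combinatorial junction database
#' (+ optional de novo junction import), per-sample read mapping with
#' 3' truncation rescue, junction counting and normalization,
#' WT-vs-KO regulation calls, PTC prediction, splice-event
#' classification with PSI/delta-PSI, and (when a conservation track
#' is supplied) the conservation analyses.  The run is reproducible
#' from its inputs and parameters alone.
#'
#' @param models list of [gene_model()] (or a GTF path).
#' @param genome named [Biostrings::DNAStringSet] (or a FASTA path).
#' @param reads named list with elements `WT` and `KO`, each a named
#'   [Biostrings::DNAStringSet] or FASTA/FASTQ path; alternatively
#'   SAM/BAM paths via `sam = TRUE`.
#' @param flank_len junction flank length (default 70).
#' @param params a [mapping_params()].
#' @param norm_method see [normalization_factors()].
#' @param min_reads regulation read cutoff (default 3).
#' @param ptc_min_dist 50-nt-rule distance (default 50).
#' @param dpsi_threshold delta-PSI call threshold in percent points
#'   (default 20).
#' @param min_event_reads PSI support threshold (default 10).
#' @param sam interpret `reads` entries as SAM/BAM paths.
#' @param denovo_bed optional junction BED to import before mapping.
#' @param track optional `cons_track` for the conservation stage.
#' @return a `splicejudge_run` list: `db`, `assignments` (per
#'   sample), `counts` (junctions x samples), `factors`,
#'   `regulation`, `ptc`, `events`, `psi`, `event_labels`,
#'   `gene_expression`, `junction_rpkm`, `summary`.
#' @export
run_pipeline <- function(models, genome, reads, flank_len = 70L,
                         params = mapping_params(),
                         norm_method = "tmm", min_reads = 3L,
                         ptc_min_dist = 50L, dpsi_threshold = 20,
                         min_event_reads = 10L, sam = FALSE,
                         denovo_bed = NULL, track = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(models)) models <- load_gene_models(models, "gtf")
  if (!all(c("WT", "KO") %in% names(reads)))
    stop("reads must be a named list with WT and KO samples")
  db <- build_combinatorial_db(models, genome, flank_len = flank_len)
  if (!is.null(denovo_bed))
    db <- import_denovo_junctions(db, denovo_bed, genome)
  assignments <- list()
  for (s in c("WT", "KO")) {
    if (sam) {
      assignments[[s]] <- import_sam(reads[[s]], db, genome)
    } else {
      rs <- as_read_set(reads[[s]])
      first <- map_reads(rs, db, genome, params)
      un <- first$target == "unmapped"
      if (any(un)) {
        rescued <- truncate_and_rescue(rs[first$read_id[un]], db, genome,
                                       params)
        first[un, ] <- rescued[match(first$read_id[un], rescued$read_id), ]
      }
      assignments[[s]] <- first
    }
  }
  counts <- vapply(assignments, count_junctions, db = db,
                   FUN.VALUE = numeric(nrow(db$junctions)))
  mapped <- vapply(assignments, function(a) sum(a$target != "unmapped"),
                   numeric(1))
  factors <- normalization_factors(counts, method = norm_method)
  regulation <- call_regulation(counts[, "WT"], counts[, "KO"],
                                factors[["WT"]], factors[["KO"]],
                                min_reads = min_reads)
  regulation <- cbind(junction_id = db$junctions$junction_id, regulation)
  ptc <- ptc_table(db, genome, ptc_min_dist = ptc_min_dist)
  jr <- vapply(c("WT", "KO"), function(s)
    rpkm(counts[, s], 2L * db$flank_len, max(mapped[[s]], 1L)),
    numeric(nrow(db$junctions)))
  events <- classify_events(db, counts)
  psi <- do.call(rbind, lapply(events, compute_delta_psi,
                               counts_wt = counts[, "WT"],
                               counts_ko = counts[, "KO"],
                               threshold = dpsi_threshold,
                               min_event_reads = min_event_reads))
  event_labels <- vapply(events, classify_inclusion_exclusion, calls = ptc,
                         FUN.VALUE = character(1))
  genex <- lapply(assignments, gene_expression, models = models)
  run <- structure(list(db = db, assignments = assignments,
                        counts = counts, mapped = mapped,
                        factors = factors, regulation = regulation,
                        ptc = ptc, junction_rpkm = jr, events = events,
                        psi = psi, event_labels = event_labels,
                        gene_expression = genex),
                   class = "splicejudge_run")
  if (!is.null(track)) run$conservation <- run_conservation(run, track)
  run$summary <- summary_report(run)
  run
}

#' @export
print.splicejudge_run <- function(x, ...) {
  cat("splicejudge run:", nrow(x$db$junctions), "junctions,",
      length(x$events), "events\n")
  invisible(x)
}

# canonical junction = consecutive exon pair of the backbone (longest
# CDS-bearing) isoform
canonical_flags <- function(db) {
  keys <- character(0)
  for (g in db$models) {
    iso <- longest_isoform(g, cds_only = TRUE)
    if (is.null(iso)) iso <- longest_isoform(g)
    ex <- iso$exons
    if (nrow(ex) < 2L) next
    for (i in seq_len(nrow(ex) - 1L)) {
      if (g$strand == "+")
        keys <- c(keys, paste(g$chrom, "+", ex$end[i], ex$start[i + 1L],
                              sep = "|"))
      else keys <- c(keys, paste(g$chrom, "-", ex$start[i], ex$end[i + 1L],
                                 sep = "|"))
    }
  }
  paste(db$junctions$chrom, db$junctions$strand, db$junctions$donor,
        db$junctions$acceptor, sep = "|") %in% keys
}

#' Tabular summary of a pipeline run
#'
#' Recomputable from the per-junction tables alone: per-sample mapping
#' category tallies; regulation tallies for all junctions and for
#' PTC+ junctions only; the canonical-vs-AS split with PTC fractions
#' of upregulated junctions; the per-class event table (total events,
#' PTC+ events, inclusion/exclusion calls and their PTC subsets); and
#' per-gene AS/PTC slopes.
#'
#' @param run a `splicejudge_run`.
#' @return list of data.frames.
#' @export
summary_report <- function(run) {
  cats <- c("genome_exonic", "junction", "genome_intronic",
            "genome_intergenic", "unmapped")
  mapping <- t(vapply(run$assignments, function(a)
    vapply(cats, function(ct) sum(a$target == ct), numeric(1)),
    numeric(length(cats))))
  expressed <- run$regulation$status != "below_cutoff"
  reg_tab <- function(sel) {
    s <- run$regulation$status[sel & expressed]
    data.frame(upregulated = sum(s == "upregulated"),
               downregulated = sum(s == "downregulated"),
               unregulated = sum(s == "unregulated"),
               total = sum(sel & expressed))
  }
  is_ptc <- !is.na(run$ptc$is_ptc) & run$ptc$is_ptc
  all_j <- rep(TRUE, nrow(run$regulation))
  regulation <- rbind(cbind(set = "all", reg_tab(all_j)),
                      cbind(set = "ptc_plus", reg_tab(is_ptc)))
  canon <- canonical_flags(run$db)
  up <- run$regulation$status == "upregulated"
  as_split <- do.call(rbind, lapply(c(canonical = TRUE, alternative = FALSE),
    function(v) {
      sel <- (canon == v) & expressed
      data.frame(n = sum(sel), upregulated = sum(sel & up),
                 up_ptc_plus = sum(sel & up & is_ptc),
                 up_ptc_fraction = if (sum(sel & up) > 0)
                   sum(sel & up & is_ptc) / sum(sel & up) else NA_real_)
    }))
  as_split <- cbind(set = c("canonical", "alternative"), as_split)
  ev_tab <- event_class_table(run)
  slopes <- tryCatch(per_gene_slopes(gene_junction_stats(run)),
                     error = function(e) NULL)
  list(mapping = as.data.frame(mapping), regulation = regulation,
       canonical_vs_as = as_split, event_classes = ev_tab,
       slopes = slopes)
}

# Table 1-shaped per-class tally
event_class_table <- function(run) {
  psi <- run$psi
  if (is.null(psi) || nrow(psi) == 0L)
    return(data.frame(cls = character(), total = integer(),
                      ptc_events = integer(), inclusion = integer(),
                      ptc_on_inclusion = integer(), exclusion = integer(),
                      ptc_on_exclusion = integer()))
  lab <- run$event_labels[psi$event_id]
  rows <- lapply(c("SES", "MES", "A5SS", "A3SS", "MXE", "AFE", "ALE"),
    function(cl) {
      sel <- psi$cls == cl
      inc <- sel & !is.na(psi$call) & psi$call == "increased_inclusion"
      exc <- sel & !is.na(psi$call) & psi$call == "increased_exclusion"
      ptc_n <- if (cl == "ALE") NA_integer_ else
        sum(sel & !is.na(lab) & lab %in% c("ptc_on_inclusion",
                                           "ptc_on_exclusion", "both_ptc"))
      data.frame(cls = cl, total = sum(sel), ptc_events = ptc_n,
                 inclusion = sum(inc),
                 ptc_on_inclusion = if (cl == "ALE") NA_integer_ else
                   sum(sel & !is.na(lab) & lab == "ptc_on_inclusion"),
                 exclusion = sum(exc),
                 ptc_on_exclusion = if (cl == "ALE") NA_integer_ else
                   sum(sel & !is.na(lab) & lab == "ptc_on_exclusion"))
    })
  do.call(rbind, rows)
}

# per-gene junction tallies feeding the slope statistic
gene_junction_stats <- function(run, sample = "KO", min_reads = 0L) {
  canon <- canonical_flags(run$db)
  is_ptc <- !is.na(run$ptc$is_ptc) & run$ptc$is_ptc
  expressed <- run$counts[, sample] > min_reads
  genes <- unique(run$db$junctions$gene_id)
  do.call(rbind, lapply(genes, function(g) {
    sel <- run$db$junctions$gene_id == g & expressed
    data.frame(gene_id = g, n_junctions = sum(sel),
               n_as = sum(sel & !canon), n_ptc = sum(sel & is_ptc))
  }))
}

#' Per-gene AS and PTC slopes
#'
#' Least-squares slopes through the origin of the number of
#' alternative-splicing junctions (and of PTC+ junctions) against the
#' total number of expressed junctions per gene: a gene with zero
#' junctions has zero AS junctions by definition, so the regression
#' is origin-anchored.  The slope is the average fraction of a gene's
#' junction complement that is AS (PTC+).
#'
#' @param stats data.frame with `n_junctions`, `n_as`, `n_ptc` per
#'   gene (see the summary report), or any columns `x`/`y` via
#'   `as_slope`/`ptc_slope` below.
#' @return list with `as_slope` and `ptc_slope`.
#' @export
per_gene_slopes <- function(stats) {
  if (nrow(stats) < 3L) stop("need >= 3 genes for slope estimation")
  origin_slope <- function(x, y) {
    if (sum(x^2) == 0) return(0)
    sum(x * y) / sum(x^2)
  }
  list(as_slope = origin_slope(stats$n_junctions, stats$n_as),
       ptc_slope = origin_slope(stats$n_junctions, stats$n_ptc))
}

#' Subsample assignments to a fixed mapped-read depth
#'
#' Stochastically removes mapped reads so all samples can be
#' normalized to the smallest library before per-gene comparisons;
#' seeded for reproducibility.
#'
#' @param assignments per-sample assignment data.frame.
#' @param n target number of mapped reads.
#' @param seed RNG seed.
#' @return thinned assignment data.frame (unmapped rows retained).
#' @export
subsample_assignments <- function(assignments, n, seed = 1L) {
  mapped <- which(assignments$target != "unmapped")
  if (length(mapped) <= n) return(assignments)
  keep <- with_seed(seed, sample(mapped, n))
  assignments[sort(c(keep, which(assignments$target == "unmapped"))), ,
              drop = FALSE]
}

#' Export genome-browser tracks
#'
#' Writes, per sample, a junction BED12 track (score = read count;
#' every junction with at least one read is exported, no minimum read
#' cutoff) and an exon-coverage bedGraph computed by piling up the
#' genomic read placements.
#'
#' @param run a `splicejudge_run`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
export_browser_tracks <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  rl_guess <- function(a) 75L
  for (s in names(run$assignments)) {
    bed <- file.path(dir, paste0("junctions_", s, ".bed"))
    write_junction_bed(run$db, bed, scores = run$counts[, s],
                       track_name = paste0("junctions_", s))
    a <- run$assignments[[s]]
    g <- a[a$target %in% c("genome_exonic", "genome_intronic",
                           "genome_intergenic") & !is.na(a$pos), ,
           drop = FALSE]
    bg <- file.path(dir, paste0("coverage_", s, ".bedGraph"))
    con <- file(bg, "w")
    writeLines(sprintf('track type=bedGraph name="coverage_%s"', s), con)
    if (nrow(g)) {
      w <- rl_guess(a)
      for (chrom in unique(g$chrom)) {
        sub <- g[g$chrom == chrom, ]
        cov <- IRanges::coverage(IRanges::IRanges(start = sub$pos + 1L,
                                                  width = w))
        rl <- S4Vectors::runLength(cov)
        rv <- S4Vectors::runValue(cov)
        ends <- cumsum(rl)
        starts <- ends - rl + 1L
        nz <- rv > 0
        if (any(nz))
          writeLines(paste(chrom, starts[nz] - 1L, ends[nz], rv[nz],
                           sep = "\t"), con)
      }
    }
    close(con)
    paths <- c(paths, bed, bg)
  }
  invisible(paths)
}

#' Canonical-isoform fold change corrected for PTC+ content
#'
#' Rescales a gene-level KO/WT fold change by the non-PTC fraction of
#' the gene's junction reads in each sample, estimating the expression
#' change of the canonical (full-length-protein-coding) isoform:
#' `gene_fc * (1 - ptc_fraction_ko) / (1 - ptc_fraction_wt)`.  Flagged
#' unreliable when either PTC fraction exceeds 0.9 and undefined at
#' exactly 1.
#'
#' @param gene_fc gene-level KO/WT fold change.
#' @param ptc_fraction_wt,ptc_fraction_ko per-sample fraction of the
#'   gene's junction reads carried by PTC+ junctions.
#' @return data.frame with `corrected_fc` and `reliable`.
#' @export
splice_factor_canonical_correction <- function(gene_fc, ptc_fraction_wt,
                                               ptc_fraction_ko) {
  undef <- ptc_fraction_wt >= 1 | ptc_fraction_ko >= 1
  fc <- ifelse(undef, NA_real_,
               gene_fc * (1 - ptc_fraction_ko) / (1 - ptc_fraction_wt))
  data.frame(corrected_fc = fc,
             reliable = !undef & ptc_fraction_wt <= 0.9 &
               ptc_fraction_ko <= 0.9)
}

# conservation stage glue: SES anchor sets from classified events +
# regulation status, PTC anchors from upregulated PTC+ junctions
run_conservation <- function(run, track) {
  anchors <- ses_anchor_sets(run)
  profiles <- if (length(anchors))
    profile_ses(anchors, track) else NULL
  up <- run$regulation$status == "upregulated"
  is_ptc <- !is.na(run$ptc$is_ptc) & run$ptc$is_ptc
  sel <- up & is_ptc & !is.na(run$ptc$stop_gpos)
  ptc_profile <- NULL
  if (any(sel)) {
    pa <- data.frame(chrom = run$ptc$stop_chrom[sel],
                     strand = run$db$junctions$strand[sel],
                     gpos = run$ptc$stop_gpos[sel],
                     exon_start = run$ptc$stop_exon_start[sel],
                     exon_end = run$ptc$stop_exon_end[sel])
    be <- expressed_exons(run)
    if (nrow(be))
      ptc_profile <- profile_ptc(pa, track, be)
  }
  list(ses_profiles = profiles, ptc_profile = ptc_profile)
}

# exons of genes with any expressed junction, for baselines
expressed_exons <- function(run) {
  expressed_genes <- unique(
    run$db$junctions$gene_id[rowSums(run$counts) > 0])
  do.call(rbind, lapply(run$db$models[
    intersect(names(run$db$models), expressed_genes)], function(g)
      data.frame(chrom = g$chrom, strand = g$strand,
                 start = g$exon_union$start, end = g$exon_union$end)))
}

# regulated/unregulated SES anchor sets keyed by PTC label and
# delta-PSI direction
ses_anchor_sets <- function(run, dpsi_threshold = 20) {
  psi <- run$psi
  if (is.null(psi) || nrow(psi) == 0L) return(list())
  ses <- psi[psi$cls == "SES" & !is.na(psi$delta_psi), , drop = FALSE]
  if (nrow(ses) == 0L) return(list())
  lab <- run$event_labels[ses$event_id]
  sets <- list()
  add_anchor <- function(name, eid) {
    ev <- run$events[[eid]]
    g <- run$db$models[[ev$gene_id]]
    uni <- g$exon_union
    cas <- ev$affected_exons[1]
    skip <- run$db$junctions[
      run$db$junctions$junction_id == ev$exclusion[1], ]
    up <- skip$donor_exon; down <- skip$acceptor_exon
    row <- data.frame(chrom = g$chrom, strand = g$strand,
                      up_start = uni$start[up], up_end = uni$end[up],
                      cas_start = uni$start[cas], cas_end = uni$end[cas],
                      down_start = uni$start[down],
                      down_end = uni$end[down])
    sets[[name]] <<- rbind(sets[[name]], row)
  }
  for (i in seq_len(nrow(ses))) {
    ptc <- !is.na(lab[i]) && lab[i] %in% c("ptc_on_inclusion",
                                           "ptc_on_exclusion", "both_ptc")
    d <- ses$delta_psi[i]
    name <- if (d < -dpsi_threshold)
      paste0(if (ptc) "ptc" else "nonptc", "_exclusion")
    else if (d > dpsi_threshold)
      paste0(if (ptc) "ptc" else "nonptc", "_inclusion")
    else "unregulated"
    add_anchor(name, ses$event_id[i])
  }
  sets
}
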