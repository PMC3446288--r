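#' Infer splice events from the expressed junction graph
#'
#' Detects the seven major alternative-splicing event classes by
#' motif search on the per-gene graph of expressed junctions (a
#' junction is expressed when it has at least `min_count` reads in any
#' sample):
#'
#' * **SES** -- a skip junction i->k together with both inclusion
#'   junctions i->j, j->k across a single intervening exon j;
#' * **MES** -- a skip junction spanning a chain of >= 2 intervening
#'   exons, each consecutive pair linked by an expressed inclusion
#'   junction;
#' * **A5SS / A3SS** -- two junctions sharing an acceptor (donor)
#'   whose donor (acceptor) exons are overlapping boundary variants;
#' * **MXE** -- exons j, k (j 5' of k, non-overlapping) with
#'   i->j, j->m, i->k, k->m all expressed and *no* expressed j->k
#'   junction (the stringent criterion: one read on j->k destroys the
#'   call, surfacing double-inclusion of both exons instead);
#' * **AFE / ALE** -- junctions from two non-overlapping 5'-terminal
#'   (3'-terminal) exons converging on one acceptor (diverging from
#'   one donor), a terminal exon being one that never appears
#'   downstream (upstream) of any expressed junction of the gene.
#'
#' Junction combinations matching no motif remain unlabelled and are
#' reported via `attr(, "complex")`.
#'
#' @param db a `junction_db`.
#' @param counts matrix of junction read counts (rows aligned to
#'   `db$junctions`, one column per sample) or a single integer
#'   vector.
#' @param min_count expression threshold (default 1 read in any
#'   sample).
#' @return list of events; each event is a list with `event_id`,
#'   `gene_id`, `cls`, `inclusion`/`exclusion` (junction id vectors),
#'   `affected_exons` (row indices into the gene's exon union).
#' @export
classify_events <- function(db, counts, min_count = 1L) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(db$junctions))
  expressed <- apply(counts, 1, max) >= min_count
  j <- db$junctions[expressed & !is.na(db$junctions$donor_exon) &
                      !is.na(db$junctions$acceptor_exon), , drop = FALSE]
  events <- list()
  used <- character(0)
  for (gid in unique(j$gene_id)) {
    g <- db$models[[gid]]
    if (is.null(g)) next
    jj <- j[j$gene_id == gid, , drop = FALSE]
    uni <- txc_exons(g$exon_union, g$strand)
    ev <- c(find_skipping(gid, jj, uni),
            find_alt_ss(gid, jj, uni, side = "A5SS"),
            find_alt_ss(gid, jj, uni, side = "A3SS"),
            find_mxe(gid, jj, uni),
            find_terminal(gid, jj, uni, side = "AFE"),
            find_terminal(gid, jj, uni, side = "ALE"))
    events <- c(events, ev)
    used <- c(used, unlist(lapply(ev, function(e) c(e$inclusion,
                                                    e$exclusion))))
  }
  names(events) <- vapply(events, function(e) e$event_id, character(1))
  attr(events, "complex") <- setdiff(j$junction_id, used)
  events
}

make_event <- function(gene_id, cls, n, inclusion, exclusion, exons) {
  list(event_id = sprintf("%s:%s:%d", gene_id, cls, n), gene_id = gene_id,
       cls = cls, inclusion = inclusion, exclusion = exclusion,
       affected_exons = exons)
}

# SES + MES: enumerate inclusion chains under each expressed skip.
find_skipping <- function(gid, jj, uni) {
  out <- list()
  n <- 0L
  edge <- paste(jj$donor_exon, jj$acceptor_exon)
  jid_of <- function(u, v) jj$junction_id[match(paste(u, v), edge)]
  for (s in seq_len(nrow(jj))) {
    i <- jj$donor_exon[s]; k <- jj$acceptor_exon[s]
    mids <- which(uni$s >= uni$e[i] & uni$e <= uni$s[k])
    if (length(mids) == 0L) next
    # DFS over expressed inclusion links i -> mids... -> k
    chains <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (!is.na(match(paste(last, k), edge)) && length(path) > 1L)
        chains[[length(chains) + 1L]] <<- path[-1]
      nxt <- mids[uni$s[mids] >= uni$e[last]]
      for (m in nxt) if (!is.na(match(paste(last, m), edge))) grow(c(path, m))
    }
    grow(i)
    for (ch in chains) {
      n <- n + 1L
      links <- mapply(jid_of, c(i, ch), c(ch, k))
      out[[length(out) + 1L]] <- make_event(
        gid, if (length(ch) == 1L) "SES" else "MES", n,
        inclusion = unname(links), exclusion = jj$junction_id[s],
        exons = ch)
    }
  }
  out
}

# A5SS: shared acceptor coordinate, overlapping donor exon variants;
# A3SS: mirror.  Inclusion is the junction retaining more exonic
# sequence (the extended variant).
find_alt_ss <- function(gid, jj, uni, side) {
  out <- list()
  n <- 0L
  key <- if (side == "A5SS") jj$acceptor else jj$donor
  for (k in unique(key)) {
    grp <- which(key == k)
    if (length(grp) < 2L) next
    for (p in utils::combn(grp, 2L, simplify = FALSE)) {
      e1 <- if (side == "A5SS") jj$donor_exon[p[1]] else jj$acceptor_exon[p[1]]
      e2 <- if (side == "A5SS") jj$donor_exon[p[2]] else jj$acceptor_exon[p[2]]
      if (e1 == e2) next
      if (uni$s[e1] >= uni$e[e2] || uni$s[e2] >= uni$e[e1]) next  # disjoint
      len1 <- uni$e[e1] - uni$s[e1]; len2 <- uni$e[e2] - uni$s[e2]
      long <- if (len1 >= len2) 1L else 2L
      n <- n + 1L
      out[[length(out) + 1L]] <- make_event(
        gid, side, n,
        inclusion = jj$junction_id[p[long]],
        exclusion = jj$junction_id[p[3L - long]],
        exons = c(e1, e2))
    }
  }
  out
}

find_mxe <- function(gid, jj, uni) {
  out <- list()
  n <- 0L
  edge <- paste(jj$donor_exon, jj$acceptor_exon)
  has <- function(u, v) !is.na(match(paste(u, v), edge))
  jid <- function(u, v) jj$junction_id[match(paste(u, v), edge)]
  donors <- unique(jj$donor_exon)
  for (i in donors) {
    mid <- unique(jj$acceptor_exon[jj$donor_exon == i])
    if (length(mid) < 2L) next
    for (p in utils::combn(sort(mid), 2L, simplify = FALSE)) {
      jx <- p[1]; kx <- p[2]
      if (uni$e[jx] > uni$s[kx]) next      # overlapping: boundary variants
      if (has(jx, kx)) next                # forbidden junction expressed
      ms <- intersect(jj$acceptor_exon[jj$donor_exon == jx],
                      jj$acceptor_exon[jj$donor_exon == kx])
      ms <- ms[uni$s[ms] >= uni$e[kx]]
      for (m in ms) {
        n <- n + 1L
        out[[length(out) + 1L]] <- make_event(
          gid, "MXE", n,
          inclusion = c(jid(i, jx), jid(jx, m)),
          exclusion = c(jid(i, kx), jid(kx, m)),
          exons = c(jx, kx))
      }
    }
  }
  out
}

# AFE: two non-overlapping 5'-terminal exons converging on one
# acceptor coordinate; ALE mirror.  Inclusion is the junction of the
# proximal alternative exon (closest to the shared boundary).
find_terminal <- function(gid, jj, uni, side) {
  out <- list()
  n <- 0L
  if (side == "AFE") {
    terminal <- setdiff(unique(jj$donor_exon), jj$acceptor_exon)
    key <- jj$acceptor
    exon_of <- jj$donor_exon
  } else {
    terminal <- setdiff(unique(jj$acceptor_exon), jj$donor_exon)
    key <- jj$donor
    exon_of <- jj$acceptor_exon
  }
  cand <- which(exon_of %in% terminal)
  for (k in unique(key[cand])) {
    grp <- cand[key[cand] == k]
    ex <- exon_of[grp]
    if (length(unique(ex)) < 2L) next
    grp <- grp[!duplicated(ex)]
    ex <- exon_of[grp]
    for (p in utils::combn(seq_along(grp), 2L, simplify = FALSE)) {
      a <- ex[p[1]]; b <- ex[p[2]]
      if (!(uni$e[a] <= uni$s[b] || uni$e[b] <= uni$s[a])) next  # overlap
      # proximal = nearer the shared boundary in transcript order
      prox <- if (side == "AFE") {
        if (uni$e[a] > uni$e[b]) 1L else 2L
      } else {
        if (uni$s[a] < uni$s[b]) 1L else 2L
      }
      n <- n + 1L
      out[[length(out) + 1L]] <- make_event(
        gid, side, n,
        inclusion = jj$junction_id[grp[p[prox]]],
        exclusion = jj$junction_id[grp[p[3L - prox]]],
        exons = c(a, b))
    }
  }
  out
}

#' Percent spliced in for one event
#'
#' `PSI = 100 * I / (I + E)` where `I` and `E` are the mean read
#' counts over the event's inclusion and exclusion junction sets (the
#' mean, not the sum, so a skipping event's two inclusion junctions
#' are not double-weighted against its one skip junction).
#'
#' @param event an event from [classify_events()].
#' @param counts named numeric vector of junction counts for one
#'   sample (names = junction ids).
#' @return PSI in `[0, 100]`, or `NA` when the event has no reads.
#' @export
compute_psi <- function(event, counts) {
  i <- mean(counts[event$inclusion])
  e <- mean(counts[event$exclusion])
  if (is.na(i) || is.na(e) || i + e == 0) return(NA_real_)
  100 * i / (i + e)
}

#' Delta-PSI between two conditions
#'
#' `delta_psi = PSI(KO) - PSI(WT)`; events whose PSI shift exceeds the
#' threshold are called `increased_inclusion` (> threshold) or
#' `increased_exclusion` (< -threshold).  An event is `supported` only
#' when PSI is defined in both samples and the summed event reads per
#' sample reach `min_event_reads`.
#'
#' @param event an event from [classify_events()].
#' @param counts_wt,counts_ko named junction count vectors.
#' @param threshold percent-point call threshold (default 20).
#' @param min_event_reads minimum summed reads over the event's
#'   junctions in each sample (default 10).
#' @return one-row data.frame: `event_id`, `gene_id`, `cls`,
#'   `psi_wt`, `psi_ko`, `delta_psi`, `call`, `supported`.
#' @export
compute_delta_psi <- function(event, counts_wt, counts_ko, threshold = 20,
                              min_event_reads = 10L) {
  psi_wt <- compute_psi(event, counts_wt)
  psi_ko <- compute_psi(event, counts_ko)
  ids <- c(event$inclusion, event$exclusion)
  supp <- !is.na(psi_wt) && !is.na(psi_ko) &&
    sum(counts_wt[ids]) >= min_event_reads &&
    sum(counts_ko[ids]) >= min_event_reads
  delta <- if (is.na(psi_wt) || is.na(psi_ko)) NA_real_ else psi_ko - psi_wt
  call <- if (is.na(delta)) NA_character_
    else if (delta > threshold) "increased_inclusion"
    else if (delta < -threshold) "increased_exclusion"
    else "none"
  data.frame(event_id = event$event_id, gene_id = event$gene_id,
             cls = event$cls, psi_wt = psi_wt, psi_ko = psi_ko,
             delta_psi = delta, call = call, supported = supp)
}
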