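# Independent oracles.  These re-derive expected results through
# different mechanics than the package (plain string/loop arithmetic,
# exhaustive enumeration), so agreement is informative.

# ---- PTC oracle -----------------------------------------------------
# Full-isoform construction + translation + 50-nt rule, all in plain
# base R on the forward strand: reverse-strand problems are first
# reflected into equivalent forward-strand ones.
.oracle_chrom_cache <- new.env(parent = emptyenv())

oracle_ptc <- function(gene, ref, j, genome, min_dist = 50L) {
  ck <- paste0(gene$chrom, ":", substr(as.character(
    Biostrings::subseq(genome[[gene$chrom]], 1, 20)), 1, 20))
  if (is.null(.oracle_chrom_cache[[ck]]))
    .oracle_chrom_cache[[ck]] <- list(
      fwd = as.character(genome[[gene$chrom]]),
      rev = as.character(Biostrings::reverseComplement(
        genome[[gene$chrom]])))
  chrom_seq <- .oracle_chrom_cache[[ck]]$fwd
  ex <- ref$exons
  donor <- j$donor; acceptor <- j$acceptor
  uni <- gene$exon_union
  if (gene$strand == "-") {
    L <- nchar(chrom_seq)
    chrom_seq <- .oracle_chrom_cache[[ck]]$rev
    refl <- function(df) data.frame(start = L - df$end, end = L - df$start)
    ex <- refl(ex)
    uni <- refl(uni)
    d0 <- L - donor; a0 <- L - acceptor
    donor <- d0; acceptor <- a0
  }
  ex <- ex[order(ex$start), , drop = FALSE]
  uni <- uni[order(uni$start), , drop = FALSE]
  # upstream chain
  up <- list()
  for (i in seq_len(nrow(ex))) {
    if (ex$end[i] <= donor) up[[length(up) + 1L]] <- c(ex$start[i], ex$end[i])
    else if (ex$start[i] < donor && ex$end[i] > donor)
      up[[length(up) + 1L]] <- c(ex$start[i], donor)
  }
  on_boundary <- length(up) > 0 && up[[length(up)]][2] == donor
  if (!on_boundary) {
    cand <- which(uni$end == donor)
    if (length(cand) == 0L) stop("oracle: donor unresolvable")
    cand <- cand[which.max(uni$end[cand] - uni$start[cand])]
    up <- Filter(function(iv) iv[2] <= uni$start[cand], up)
    up[[length(up) + 1L]] <- c(uni$start[cand], donor)
  }
  if (length(up) == 0L) stop("oracle: junction outside reference")
  # downstream chain
  dn <- list()
  inside <- which(ex$start <= acceptor & ex$end > acceptor)
  if (length(inside)) {
    i <- inside[1]
    dn[[1]] <- c(acceptor, ex$end[i])
    for (k in seq_len(nrow(ex)))
      if (ex$start[k] >= ex$end[i]) dn[[length(dn) + 1L]] <- c(ex$start[k],
                                                              ex$end[k])
  } else {
    cand <- which(uni$start == acceptor)
    if (length(cand) == 0L) stop("oracle: acceptor unresolvable")
    cand <- cand[which.max(uni$end[cand] - uni$start[cand])]
    dn[[1]] <- c(acceptor, uni$end[cand])
    for (k in seq_len(nrow(ex)))
      if (ex$start[k] >= uni$end[cand])
        dn[[length(dn) + 1L]] <- c(ex$start[k], ex$end[k])
  }
  chain <- c(up, dn)
  tx <- paste(vapply(chain, function(iv)
    substr(chrom_seq, iv[1] + 1L, iv[2]), character(1)), collapse = "")
  lens <- vapply(chain, function(iv) iv[2] - iv[1], numeric(1))
  last_junction <- sum(lens) - lens[length(lens)]
  if (length(chain) == 1L) last_junction <- NA_integer_
  # map reference cds_start to a genomic base, then into the chain
  walk_to_genomic <- function(exdf, off) {
    for (i in seq_len(nrow(exdf))) {
      w <- exdf$end[i] - exdf$start[i]
      if (off < w) return(exdf$start[i] + off)
      off <- off - w
    }
    NA_integer_
  }
  g_cds <- walk_to_genomic(ex, ref$cds_start)
  cds <- NA_integer_
  off <- 0L
  for (iv in chain) {
    if (g_cds >= iv[1] && g_cds < iv[2]) { cds <- off + g_cds - iv[1]; break }
    off <- off + iv[2] - iv[1]
  }
  if (is.na(cds)) return(list(is_ptc = NA))
  # translate: first stop from cds
  stops <- c("TAA", "TAG", "TGA")
  pos <- cds
  stop_pos <- NA_integer_; stop_codon <- NA_character_
  while (pos + 3L <= nchar(tx)) {
    cod <- substr(tx, pos + 1L, pos + 3L)
    if (cod %in% stops) { stop_pos <- pos; stop_codon <- cod; break }
    pos <- pos + 3L
  }
  if (is.na(stop_pos)) return(list(is_ptc = FALSE, no_stop = TRUE))
  dist <- if (is.na(last_junction)) NA_integer_
          else last_junction - (stop_pos + 3L)
  # annotated stop of the reference itself
  ref_tx <- paste(vapply(seq_len(nrow(ex)), function(i)
    substr(chrom_seq, ex$start[i] + 1L, ex$end[i]), character(1)),
    collapse = "")
  rp <- ref$cds_start
  ref_stop_g <- NA_integer_
  while (rp + 3L <= nchar(ref_tx)) {
    if (substr(ref_tx, rp + 1L, rp + 3L) %in% stops) {
      ref_stop_g <- walk_to_genomic(ex, rp)
      break
    }
    rp <- rp + 3L
  }
  stop_g <- NA_integer_
  off <- 0L
  for (iv in chain) {
    w <- iv[2] - iv[1]
    if (stop_pos < off + w) { stop_g <- iv[1] + stop_pos - off; break }
    off <- off + w
  }
  annotated <- !is.na(ref_stop_g) && identical(ref_stop_g, stop_g)
  list(is_ptc = !is.na(dist) && dist >= min_dist && !annotated,
       stop_codon = stop_codon, dist = dist)
}

# ---- splice-event motif oracle -------------------------------------
# Exhaustive enumeration over exon tuples of one gene.  `edges` is a
# data.frame with donor_exon/acceptor_exon/junction_id of expressed
# junctions; `uni` the gene's exon union in transcript coordinates
# (columns s, e).  Returns a character vector of canonical event keys
# "cls|inclusion ids|exclusion ids" for set comparison.
oracle_event_keys <- function(edges, uni) {
  E <- paste(edges$donor_exon, edges$acceptor_exon)
  has <- function(u, v) paste(u, v) %in% E
  jid <- function(u, v) edges$junction_id[match(paste(u, v), E)]
  key <- function(cls, inc, exc)
    paste(cls, paste(sort(inc), collapse = ","),
          paste(sort(exc), collapse = ","), sep = "|")
  n <- nrow(uni)
  keys <- character(0)
  overlap <- function(a, b) !(uni$e[a] <= uni$s[b] || uni$e[b] <= uni$s[a])
  # skipping (SES m=1, MES m>=2): all ordered subsets of intervening
  # exons forming an expressed chain
  for (r in which(rep(TRUE, nrow(edges)))) {
    i <- edges$donor_exon[r]; k <- edges$acceptor_exon[r]
    mids <- which(uni$s >= uni$e[i] & uni$e <= uni$s[k])
    if (!length(mids)) next
    for (m in seq_along(mids)) {
      if (length(mids) < m) next
      for (ss in utils::combn(mids, m, simplify = FALSE)) {
        ch <- sort(ss)
        ok <- TRUE
        for (q in seq_len(m - 1L))
          if (uni$e[ch[q]] > uni$s[ch[q + 1L]]) { ok <- FALSE; break }
        if (!ok) next
        path <- c(i, ch, k)
        if (all(mapply(has, path[-length(path)], path[-1]))) {
          inc <- mapply(jid, path[-length(path)], path[-1])
          keys <- c(keys, key(if (m == 1L) "SES" else "MES", inc,
                              jid(i, k)))
        }
      }
    }
  }
  # A5SS / A3SS
  for (r1 in seq_len(nrow(edges))) for (r2 in seq_len(nrow(edges))) {
    if (r1 >= r2) next
    d1 <- edges$donor_exon[r1]; d2 <- edges$donor_exon[r2]
    a1 <- edges$acceptor_exon[r1]; a2 <- edges$acceptor_exon[r2]
    if (edges$acceptor[r1] == edges$acceptor[r2] && d1 != d2 &&
        overlap(d1, d2))
      keys <- c(keys, key("A5SS",
                          edges$junction_id[if ((uni$e[d1] - uni$s[d1]) >=
                                                (uni$e[d2] - uni$s[d2]))
                                            r1 else r2],
                          edges$junction_id[if ((uni$e[d1] - uni$s[d1]) >=
                                                (uni$e[d2] - uni$s[d2]))
                                            r2 else r1]))
    if (edges$donor[r1] == edges$donor[r2] && a1 != a2 && overlap(a1, a2))
      keys <- c(keys, key("A3SS",
                          edges$junction_id[if ((uni$e[a1] - uni$s[a1]) >=
                                                (uni$e[a2] - uni$s[a2]))
                                            r1 else r2],
                          edges$junction_id[if ((uni$e[a1] - uni$s[a1]) >=
                                                (uni$e[a2] - uni$s[a2]))
                                            r2 else r1]))
  }
  # MXE
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    for (m in seq_len(n)) {
      if (j >= k || overlap(j, k)) next
      if (!(uni$s[j] >= uni$e[i] && uni$s[k] >= uni$e[j] - 0 &&
            uni$s[m] >= uni$e[k])) next
      if (has(i, j) && has(j, m) && has(i, k) && has(k, m) && !has(j, k))
        keys <- c(keys, key("MXE", c(jid(i, j), jid(j, m)),
                            c(jid(i, k), jid(k, m))))
    }
  # AFE / ALE
  starters <- setdiff(unique(edges$donor_exon), edges$acceptor_exon)
  enders <- setdiff(unique(edges$acceptor_exon), edges$donor_exon)
  for (r1 in seq_len(nrow(edges))) for (r2 in seq_len(nrow(edges))) {
    if (r1 == r2) next
    f1 <- edges$donor_exon[r1]; f2 <- edges$donor_exon[r2]
    if (f1 %in% starters && f2 %in% starters && f1 < f2 &&
        !overlap(f1, f2) && edges$acceptor[r1] == edges$acceptor[r2]) {
      prox <- if (uni$e[f1] > uni$e[f2]) r1 else r2
      keys <- c(keys, key("AFE", edges$junction_id[prox],
                          edges$junction_id[if (prox == r1) r2 else r1]))
    }
    l1 <- edges$acceptor_exon[r1]; l2 <- edges$acceptor_exon[r2]
    if (l1 %in% enders && l2 %in% enders && l1 < l2 && !overlap(l1, l2) &&
        edges$donor[r1] == edges$donor[r2]) {
      prox <- if (uni$s[l1] < uni$s[l2]) r1 else r2
      keys <- c(keys, key("ALE", edges$junction_id[prox],
                          edges$junction_id[if (prox == r1) r2 else r1]))
    }
  }
  unique(keys)
}

event_keys <- function(events) {
  unique(vapply(events, function(e)
    paste(e$cls, paste(sort(e$inclusion), collapse = ","),
          paste(sort(e$exclusion), collapse = ","), sep = "|"),
    character(1)))
}

# ---- Fisher 2x2 enumeration oracle ---------------------------------
# two-sided p by summing probabilities of all tables (fixed margins)
# no more likely than the observed one
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(c1, r1)
  probs <- vapply(lo:hi, function(a)
    stats::dhyper(a, r1, r2, c1), numeric(1))
  obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# ---- brute-force read mapping oracle -------------------------------
# exhaustive substring search with the package's documented policy
oracle_map <- function(reads, db, genome, anchor = 5L) {
  jseq <- db$junctions$seq
  out <- character(length(reads))
  for (i in seq_along(reads)) {
    r <- as.character(reads[[i]])
    w <- nchar(r)
    if (w < 2L * anchor) { out[i] <- "unmapped"; next }
    hits <- character(0)
    for (jx in seq_along(jseq)) {
      p <- regexpr(r, jseq[jx], fixed = TRUE)
      while (p != -1L) {
        fu <- db$junctions$flank_up[jx]
        if (p <= fu - anchor + 1L && p + w - 1L >= fu + anchor)
          hits <- c(hits, db$junctions$junction_id[jx])
        p2 <- regexpr(r, substring(jseq[jx], p + 1L), fixed = TRUE)
        p <- if (p2 == -1L) -1L else p + p2
      }
    }
    hits <- unique(hits)
    if (length(hits) == 1L) { out[i] <- hits; next }
    if (length(hits) > 1L) { out[i] <- "unmapped"; next }
    gl <- 0L
    for (chrom in names(genome)) {
      cs <- as.character(genome[[chrom]])
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cs)))
      for (s in c(cs, rc)) {
        p <- 1L
        repeat {
          q <- regexpr(r, substring(s, p), fixed = TRUE)
          if (q == -1L) break
          gl <- gl + 1L
          p <- p + q
        }
      }
    }
    out[i] <- if (gl == 1L) "genome" else "unmapped"
  }
  out
}
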