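# Alternative-splicing event construction and classification.
#
# An event is a set of >= 2 candidate isoform forms of one gene that share an
# anchor splice site (AFE/ALE), flanking exons (cassette/MXE), one end of a
# junction (A5SS/A3SS), or an intron (IR). Each candidate is a list of parts:
# exon parts [start,end) and junction parts (donor_end, acceptor_start).

part_exon <- function(start, end) list(kind = "E", start = start, end = end)
part_jcn <- function(d, a) list(kind = "J", start = d, end = a)

parts_string <- function(parts) {
  paste(vapply(parts, function(p) sprintf("%s:%d-%d", p$kind,
                                          as.integer(p$start),
                                          as.integer(p$end)),
               character(1)), collapse = ",")
}

#' Build and classify alternative-splicing events
#'
#' Classifies, per gene: alternative first exons (distinct first exons whose
#' first junctions share a downstream acceptor anchor), alternative last
#' exons (symmetric at a shared donor), cassette exons (skippable between
#' shared flanks), mutually exclusive exons, alternative 5'/3' splice sites
#' (junction pairs sharing one end whose varying exons share the other
#' boundary), and intron retention (an intron with both a spliced junction
#' and a spanning retained exon). Events whose parts all occur in
#' `source == "reference"` transcripts are labelled `"K"` (known), otherwise
#' `"N"` (novel). Construction is deterministic and independent of transcript
#' input order.
#'
#' @param annotation Annotation table ([read_gtf()]).
#' @param junctions Optional extra junction universe
#'   ([junctions_from_annotation()] layout) merged into each gene's junction
#'   evidence by span containment; defaults to the junctions implied by the
#'   annotation itself.
#' @return `data.frame` with one row per event candidate: `event_id`,
#'   `event_type`, `novelty`, `gene_id`, `chrom`, `strand`, `candidate`,
#'   `inclusion`, `exon_start`/`exon_end` (distinguishing exon, `NA` for
#'   junction-only candidates), `parts`, `exon_len`, `n_jcn`, `row_id`.
#' @export
build_events <- function(annotation, junctions = NULL) {
  genes <- split(annotation, annotation$gene_id)
  extra <- junctions
  all_events <- list()
  for (g in names(genes)) {
    ex <- genes[[g]]
    gx <- if (!is.null(extra)) {
      extra[extra$chrom == ex$chrom[1] &
              extra$donor_end >= min(ex$start) &
              extra$acceptor_start <= max(ex$end), , drop = FALSE]
    } else NULL
    all_events[[g]] <- gene_events(ex, gx)
  }
  ev <- do.call(rbind, all_events[order(names(all_events))])
  if (is.null(ev) || nrow(ev) == 0) {
    return(empty_events())
  }
  # deterministic ids: per gene and type, number events by leftmost coordinate
  ord <- order(ev$chrom, ev$gene_id, ev$event_type, ev$min_start, ev$parts_key)
  ev <- ev[ord, , drop = FALSE]
  key <- paste(ev$gene_id, ev$event_type, ev$min_start, ev$parts_key)
  ev$event_idx <- match(key, unique(key))
  per <- !duplicated(key)
  idx_in_gene <- stats::ave(seq_len(sum(per)),
                            paste(ev$gene_id[per], ev$event_type[per]),
                            FUN = seq_along)
  ev$event_id <- sprintf("%s_%s_%d", ev$event_type, ev$gene_id,
                         idx_in_gene[ev$event_idx])
  ev$row_id <- paste0(ev$event_id, ":", ev$candidate)
  ev <- ev[order(ev$chrom, ev$min_start, ev$event_id, ev$candidate), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev[, c("event_id", "event_type", "novelty", "gene_id", "chrom", "strand",
         "candidate", "inclusion", "exon_start", "exon_end", "parts",
         "exon_len", "n_jcn", "row_id")]
}

empty_events <- function() {
  data.frame(event_id = character(0), event_type = character(0),
             novelty = character(0), gene_id = character(0),
             chrom = character(0), strand = character(0),
             candidate = integer(0), inclusion = logical(0),
             exon_start = numeric(0), exon_end = numeric(0),
             parts = character(0), exon_len = numeric(0), n_jcn = integer(0),
             row_id = character(0), stringsAsFactors = FALSE)
}

# All events of one gene. `gx` is an optional extra junction table.
gene_events <- function(ex, gx = NULL) {
  strand <- ex$strand[1]
  chrom <- ex$chrom[1]
  txs <- lapply(split(ex, ex$transcript_id), function(tx) {
    tx[order(tx$start), , drop = FALSE]
  })
  jcn <- junctions_from_annotation(ex)
  jkey <- unique(paste(jcn$donor_end, jcn$acceptor_start))
  if (!is.null(gx) && nrow(gx)) {
    jkey <- union(jkey, paste(gx$donor_end, gx$acceptor_start))
  }
  ref_tx <- names(txs)[vapply(txs, function(t) t$source[1] == "reference",
                              logical(1))]
  ref_ekey <- unique(paste(ex$start, ex$end)[ex$transcript_id %in% ref_tx])
  ref_jkey <- unique(paste(jcn$donor_end, jcn$acceptor_start)[
    jcn$transcript_id %in% ref_tx])

  events <- list()
  add <- function(type, candidates, inclusion = 1L) {
    # candidates: list of list(parts=, exon=c(start,end) or NULL)
    events[[length(events) + 1]] <<- list(type = type,
                                          candidates = candidates,
                                          inclusion = inclusion)
  }

  # ---- AFE / ALE ----------------------------------------------------------
  terminal_groups <- function(which_end) {
    recs <- list()
    for (tx in txs) {
      m <- nrow(tx)
      if (m < 2) next
      if (which_end == "first") {
        fe <- tx[tx$rank == 1, ]
        nx <- tx[tx$rank == 2, ]
        anchor <- if (strand == "+") nx$start else nx$end
      } else {
        mr <- max(tx$rank)
        fe <- tx[tx$rank == mr, ]
        nx <- tx[tx$rank == mr - 1, ]
        anchor <- if (strand == "+") nx$end else nx$start
      }
      recs[[length(recs) + 1]] <- data.frame(anchor = anchor, s = fe$start,
                                             e = fe$end)
    }
    if (!length(recs)) return(NULL)
    r <- unique(do.call(rbind, recs))
    split(r, r$anchor)
  }
  # distinct terminal exons must be mutually non-overlapping to count as
  # alternative first/last exons; overlapping variants are splice-site events
  disjoint <- function(grp) {
    grp <- grp[order(grp$s, grp$e), , drop = FALSE]
    nrow(grp) < 2 || all(grp$s[-1] >= cummax(grp$e[-nrow(grp)]))
  }
  for (grp in terminal_groups("first") %||% list()) {
    if (nrow(grp) < 2 || !disjoint(grp)) next
    grp <- grp[order(grp$s, grp$e), , drop = FALSE]
    anchor <- grp$anchor[1]
    cands <- lapply(seq_len(nrow(grp)), function(i) {
      jp <- if (strand == "+") part_jcn(grp$e[i], anchor) else
        part_jcn(anchor, grp$s[i])
      list(parts = list(part_exon(grp$s[i], grp$e[i]), jp),
           exon = c(grp$s[i], grp$e[i]))
    })
    add("AFE", cands)
  }
  for (grp in terminal_groups("last") %||% list()) {
    if (nrow(grp) < 2 || !disjoint(grp)) next
    grp <- grp[order(grp$s, grp$e), , drop = FALSE]
    anchor <- grp$anchor[1]
    cands <- lapply(seq_len(nrow(grp)), function(i) {
      jp <- if (strand == "+") part_jcn(anchor, grp$s[i]) else
        part_jcn(grp$e[i], anchor)
      list(parts = list(part_exon(grp$s[i], grp$e[i]), jp),
           exon = c(grp$s[i], grp$e[i]))
    })
    add("ALE", cands)
  }

  # ---- flanked internal exons: cassette and MXE ---------------------------
  flanked <- list()
  for (tx in txs) {
    m <- nrow(tx)
    if (m < 3) next
    for (i in 2:(m - 1)) {
      flanked[[length(flanked) + 1]] <- data.frame(
        a = tx$end[i - 1], b = tx$start[i + 1], s = tx$start[i], e = tx$end[i])
    }
  }
  if (length(flanked)) {
    fl <- unique(do.call(rbind, flanked))
    for (fk in split(fl, paste(fl$a, fl$b))) {
      a <- fk$a[1]; b <- fk$b[1]
      skip <- paste(a, b) %in% jkey
      fk <- fk[order(fk$s, fk$e), , drop = FALSE]
      if (skip) {
        for (i in seq_len(nrow(fk))) {
          add("CASSETTE", list(
            list(parts = list(part_jcn(a, fk$s[i]),
                              part_exon(fk$s[i], fk$e[i]),
                              part_jcn(fk$e[i], b)),
                 exon = c(fk$s[i], fk$e[i])),
            list(parts = list(part_jcn(a, b)), exon = NULL)))
        }
      } else if (nrow(fk) >= 2 && disjoint(fk)) {
        cands <- lapply(seq_len(nrow(fk)), function(i) {
          list(parts = list(part_jcn(a, fk$s[i]),
                            part_exon(fk$s[i], fk$e[i]),
                            part_jcn(fk$e[i], b)),
               exon = c(fk$s[i], fk$e[i]))
        })
        add("MXE", cands)
      }
    }
  }

  # ---- A5SS / A3SS --------------------------------------------------------
  ujcn <- unique(jcn[, c("donor_end", "acceptor_start")])
  uex <- unique(ex[, c("start", "end")])
  # shared acceptor, varying donors from exon variants with a common start
  for (ga in split(ujcn, ujcn$acceptor_start)) {
    if (nrow(ga) < 2) next
    a <- ga$acceptor_start[1]
    donors <- sort(unique(ga$donor_end))
    starts_of <- lapply(donors, function(d) uex$start[uex$end == d])
    common <- Reduce(intersect, starts_of)
    if (!length(common)) next
    s <- min(common)
    type <- if (strand == "+") "A5SS" else "A3SS"
    cands <- lapply(donors, function(d) {
      list(parts = list(part_exon(s, d), part_jcn(d, a)), exon = c(s, d))
    })
    add(type, cands)
  }
  # shared donor, varying acceptors from exon variants with a common end
  for (gd in split(ujcn, ujcn$donor_end)) {
    if (nrow(gd) < 2) next
    d <- gd$donor_end[1]
    accs <- sort(unique(gd$acceptor_start))
    ends_of <- lapply(accs, function(a) uex$end[uex$start == a])
    common <- Reduce(intersect, ends_of)
    if (!length(common)) next
    e <- max(common)
    type <- if (strand == "+") "A3SS" else "A5SS"
    cands <- lapply(accs, function(a) {
      list(parts = list(part_jcn(d, a), part_exon(a, e)), exon = c(a, e))
    })
    add(type, cands)
  }

  # ---- intron retention ---------------------------------------------------
  for (i in seq_len(nrow(ujcn))) {
    d <- ujcn$donor_end[i]; a <- ujcn$acceptor_start[i]
    span <- uex[uex$start < d & uex$end > a, , drop = FALSE]
    if (!nrow(span)) next
    span <- span[order(span$start, span$end), , drop = FALSE][1, ]
    add("IR", list(
      list(parts = list(part_exon(span$start, span$end)),
           exon = c(span$start, span$end)),
      list(parts = list(part_jcn(d, a)), exon = NULL)))
  }

  if (!length(events)) return(NULL)
  rows <- lapply(events, function(evt) {
    all_parts <- unlist(lapply(evt$candidates, `[[`, "parts"),
                        recursive = FALSE)
    known <- all(vapply(all_parts, function(p) {
      if (p$kind == "E") paste(p$start, p$end) %in% ref_ekey
      else paste(p$start, p$end) %in% ref_jkey
    }, logical(1)))
    cand_rows <- lapply(seq_along(evt$candidates), function(ci) {
      cd <- evt$candidates[[ci]]
      epl <- vapply(cd$parts, function(p)
        if (p$kind == "E") p$end - p$start else 0, numeric(1))
      njc <- sum(vapply(cd$parts, function(p) p$kind == "J", logical(1)))
      data.frame(event_type = evt$type,
                 novelty = if (known) "K" else "N",
                 gene_id = ex$gene_id[1], chrom = chrom, strand = strand,
                 candidate = ci, inclusion = ci == evt$inclusion,
                 exon_start = if (is.null(cd$exon)) NA_real_ else cd$exon[1],
                 exon_end = if (is.null(cd$exon)) NA_real_ else cd$exon[2],
                 parts = parts_string(cd$parts),
                 exon_len = sum(epl), n_jcn = njc,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, cand_rows)
    out$min_start <- min(vapply(all_parts, `[[`, numeric(1), "start"))
    out$parts_key <- paste(out$parts, collapse = ";")
    out
  })
  do.call(rbind, rows)
}

#' Write the per-candidate event/count table
#'
#' One row per event candidate with its raw counts per sample appended —
#' the package's analog of a junction-count inclusion/exclusion table.
#'
#' @param events Event table ([build_events()]).
#' @param counts [count_table()] keyed by `row_id`.
#' @param path Output TSV.
#' @export
write_event_table <- function(events, counts, path) {
  m <- counts$counts[events$row_id, , drop = FALSE]
  df <- cbind(events[, c("event_id", "event_type", "novelty", "gene_id",
                         "chrom", "strand", "candidate", "inclusion",
                         "exon_start", "exon_end", "parts")],
              as.data.frame(m, check.names = FALSE))
  write_tsv(df, path)
}
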