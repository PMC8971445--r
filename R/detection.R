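# Detection and classification of rearrangements against the ancestral
# order, and screening of apparent rearrangements for annotation errors.
#
# The moved gene set is defined as the complement of a maximum-cardinality
# common signed circular subsequence between the architecture (one chosen
# copy per duplicated symbol) and the ancestral order. Because the ancestral
# order maps to increasing indices, this is a longest circularly-increasing
# subsequence problem over the ancestral indices of sign-concordant genes.

# Maximum size of a circularly-increasing subsequence of `values` (distinct
# integers in 1..period, given in circular order) that contains all of
# `forced`. Returns 0 if no such subsequence exists. Anchoring trick: any
# non-empty circular subsequence can be anchored at its first element, so we
# maximize over rotations, remapping values relative to the anchor.
.lcis_max <- function(values, period, forced = integer(0)) {
  m <- length(values)
  if (m == 0L) return(0L)
  fpos <- match(forced, values)
  if (anyNA(fpos)) stop("forced values must be present")
  best <- 0L
  for (a in seq_len(m)) {
    ord <- if (a == 1L) seq_len(m) else c(a:m, seq_len(a - 1L))
    u <- (values[ord] - values[a]) %% period
    is_forced <- ord %in% fpos
    L <- rep(-Inf, m)
    L[1L] <- 1
    last_forced <- 0L  # most recent forced rotated-position seen so far
    if (is_forced[1L]) last_forced <- 1L
    for (i in seq_len(m)[-1L]) {
      lb <- max(1L, last_forced)
      js <- seq.int(lb, i - 1L)
      js <- js[u[js] < u[i] & L[js] > 0]
      if (length(js) > 0L) L[i] <- 1 + max(L[js])
      if (is_forced[i]) last_forced <- i
    }
    ok <- if (last_forced > 0L) seq.int(last_forced, m) else seq_len(m)
    v <- suppressWarnings(max(L[ok]))
    if (is.finite(v) && v > best) best <- as.integer(v)
  }
  best
}

# Kept set of a maximum common signed circular subsequence, deterministic:
# among all maximum subsequences, the one whose sorted ancestral-index vector
# is lexicographically smallest (so ties mark the larger-index gene as
# moved). Greedy over candidate values in ascending order, checking
# extendability with a forced-set DP.
.lcis_keep <- function(values, period) {
  m <- length(values)
  if (m == 0L) return(integer(0))
  # fast path: already circularly increasing (at most one circular descent)
  if (sum(diff(c(values, values[1L])) < 0) <= 1L) return(values)
  total <- .lcis_max(values, period)
  forced <- integer(0)
  for (x in sort(values)) {
    if (length(forced) == total) break
    if (.lcis_max(values, period, forced = c(forced, x)) == total) {
      forced <- c(forced, x)
    }
  }
  forced
}

# For each symbol with several non-pseudo copies, pick the copy whose signed
# neighbourhood best matches the ancestral context (shared signed
# adjacencies with the ancestral order); ties keep the smallest copy_index.
# Returns a logical vector over the rows of `g` (non-pseudo gene table).
.chosen_copies <- function(g) {
  n <- nrow(g)
  chosen <- rep(TRUE, n)
  idx <- unname(.ANCESTRAL_INDEX[g$symbol])
  anc <- unname(.ANCESTRAL_SIGNS[g$symbol])
  dup_symbols <- unique(g$symbol[duplicated(g$symbol)])
  if (length(dup_symbols) == 0L || n < 2L) return(chosen)
  prv <- c(n, seq_len(n - 1L))
  nxt <- c(seq_len(n)[-1L], 1L)
  adj_ok <- function(i, j, offset) {
    # is (i, j) an ancestral signed adjacency with j `offset` ahead of i?
    ((idx[j] - idx[i]) %% 37L) == offset &&
      g$sign[i] == anc[i] && g$sign[j] == anc[j]
  }
  for (s in dup_symbols) {
    rows <- which(g$symbol == s)
    score <- vapply(rows, function(i) {
      sum(adj_ok(prv[i], i, 1L), adj_ok(i, nxt[i], 1L))
    }, numeric(1))
    best <- rows[order(-score, g$copy_index[rows])][1L]
    chosen[rows] <- FALSE
    chosen[best] <- TRUE
  }
  chosen
}

#' Identify the genes moved relative to the ancestral order
#'
#' Computes a maximum-cardinality common signed circular subsequence between
#' the architecture and the ancestral order, using one chosen copy per
#' duplicated symbol (the copy whose neighbours best match the ancestral
#' context) and only genes whose strand sign matches the ancestral sign
#' (sign-flipped genes are always moved). The moved set is the complement;
#' ties between equally large subsequences are broken deterministically by
#' keeping the smaller ancestral index.
#'
#' @param arch A `mito_arch` (canonicalized internally).
#' @return An object of class `moved_report`: list with `genome_id`, `moved`
#'   and `in_place` data.frames (`symbol`, `copy_index`), which partition all
#'   non-pseudo gene occurrences, plus the logical helper columns `chosen`
#'   attribute used by [classify_events()].
#' @export
#' @examples
#' moved_gene_set(ancestral_order())$moved  # empty
moved_gene_set <- function(arch) {
  stopifnot(inherits(arch, "mito_arch"))
  arch <- canonicalize(arch)
  g <- arch$genes[!arch$genes$pseudo, , drop = FALSE]
  rownames(g) <- NULL
  chosen <- .chosen_copies(g)
  idx <- unname(.ANCESTRAL_INDEX[g$symbol])
  anc <- unname(.ANCESTRAL_SIGNS[g$symbol])
  candidate <- chosen & g$sign == anc
  kept_values <- .lcis_keep(idx[candidate], 37L)
  in_place <- candidate & idx %in% kept_values
  inst <- g[, c("symbol", "copy_index")]
  out <- list(
    genome_id = arch$genome_id,
    moved = inst[!in_place, , drop = FALSE],
    in_place = inst[in_place, , drop = FALSE]
  )
  rownames(out$moved) <- rownames(out$in_place) <- NULL
  attr(out, "chosen") <- inst[chosen, , drop = FALSE]
  class(out) <- "moved_report"
  out
}

.empty_events <- function() {
  data.frame(genome_id = character(), symbol = character(),
             copy_index = integer(), kind = character(),
             reported_class = character(), status = character(),
             reason = character(), stringsAsFactors = FALSE)
}

.event_row <- function(genome_id, symbol, copy_index, kind) {
  data.frame(
    genome_id = genome_id, symbol = symbol, copy_index = as.integer(copy_index),
    kind = kind,
    reported_class = switch(kind, duplication = "dup", deletion = "del",
                            inversion = "inv_tra", translocation = "inv_tra"),
    status = "unevaluated", reason = "none", stringsAsFactors = FALSE
  )
}

#' Classify rearrangement events for one genome
#'
#' Turns a moved-gene report into typed events: one duplication per extra
#' copy of a symbol (the non-chosen copies), one deletion per canonical
#' symbol with no non-pseudo copy, one inversion per chosen copy whose sign
#' differs from the ancestral strand, and one translocation per moved chosen
#' copy with the ancestral sign. Events start with status `unevaluated`;
#' see [screen_annotation_errors()].
#'
#' @param arch A `mito_arch`.
#' @param report The matching `moved_report`; computed from `arch` when
#'   omitted.
#' @return Event data.frame with columns `genome_id`, `symbol`, `copy_index`,
#'   `kind`, `reported_class` (`dup`/`del`/`inv_tra`), `status`, `reason`.
#' @export
classify_events <- function(arch, report = moved_gene_set(arch)) {
  stopifnot(inherits(arch, "mito_arch"), inherits(report, "moved_report"))
  arch <- canonicalize(arch)
  g <- arch$genes[!arch$genes$pseudo, , drop = FALSE]
  chosen_tab <- attr(report, "chosen")
  key <- paste(g$symbol, g$copy_index)
  chosen <- key %in% paste(chosen_tab$symbol, chosen_tab$copy_index)
  moved <- key %in% paste(report$moved$symbol, report$moved$copy_index)
  anc <- unname(.ANCESTRAL_SIGNS[g$symbol])

  rows <- list()
  dup <- which(!chosen)
  for (i in dup) {
    rows[[length(rows) + 1L]] <-
      .event_row(arch$genome_id, g$symbol[i], g$copy_index[i], "duplication")
  }
  for (s in setdiff(.ANCESTRAL_SYMBOLS, g$symbol)) {
    rows[[length(rows) + 1L]] <- .event_row(arch$genome_id, s, 1L, "deletion")
  }
  inv <- which(chosen & g$sign != anc)
  for (i in inv) {
    rows[[length(rows) + 1L]] <-
      .event_row(arch$genome_id, g$symbol[i], g$copy_index[i], "inversion")
  }
  tra <- which(chosen & g$sign == anc & moved)
  for (i in tra) {
    rows[[length(rows) + 1L]] <-
      .event_row(arch$genome_id, g$symbol[i], g$copy_index[i], "translocation")
  }
  if (length(rows) == 0L) return(.empty_events())
  out <- do.call(rbind, rows)
  out <- out[order(match(out$kind, c("duplication", "deletion", "inversion",
                                     "translocation")),
                   .ANCESTRAL_INDEX[out$symbol], out$copy_index), ]
  rownames(out) <- NULL
  out
}

#' Screen rearrangement events against sequence-verification evidence
#'
#' Reconciles detected events with an external evidence table, marking each
#' event `confirmed` or `refuted` (an annotation error). An inversion is
#' refuted (reason `wrong_strand_annotation`) when the verified strand equals
#' the ancestral sign with identity at or above the threshold: the gene sits
#' on its usual strand and only the annotation was flipped. A deletion is
#' refuted (`unannotated_not_deleted`) when the gene sequence was located in
#' the genome. A translocation or duplication is refuted (`misnamed_gene`)
#' when the annotated sequence matches the gene expected at that ancestral
#' position at or above the threshold. Events without evidence are confirmed
#' by default; only demonstrable errors are refuted.
#'
#' @param events Event data.frame from [classify_events()].
#' @param evidence Evidence data.frame (see [read_evidence_tsv()]); may be
#'   `NULL` or empty.
#' @param identity_threshold Identity fraction in (0, 1] above which evidence
#'   is accepted; default 0.80.
#' @return The events with `status` and `reason` filled in.
#' @export
screen_annotation_errors <- function(events, evidence = NULL,
                                     identity_threshold = 0.80) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1) {
    stop("identity_threshold must lie in (0, 1]")
  }
  if (nrow(events) == 0L) return(events)
  events$status <- "confirmed"
  events$reason <- "none"
  if (is.null(evidence) || nrow(evidence) == 0L) return(events)

  ekey <- paste(evidence$genome_id, evidence$symbol, evidence$copy_index)
  hit <- match(paste(events$genome_id, events$symbol, events$copy_index), ekey)
  has <- !is.na(hit)
  if (!any(has)) return(events)
  ev <- evidence[hit[has], , drop = FALSE]
  sub <- events[has, , drop = FALSE]
  anc_strand <- ifelse(.ANCESTRAL_SIGNS[sub$symbol] > 0, "+", "-")
  ident_ok <- !is.na(ev$identity_fraction) &
    ev$identity_fraction >= identity_threshold

  refute <- rep(FALSE, nrow(sub))
  reason <- rep("none", nrow(sub))

  inv <- sub$kind == "inversion" & ev$verified_strand == anc_strand & ident_ok
  refute[inv] <- TRUE; reason[inv] <- "wrong_strand_annotation"

  del <- sub$kind == "deletion" & ev$located
  refute[del] <- TRUE; reason[del] <- "unannotated_not_deleted"

  mis <- sub$kind %in% c("translocation", "duplication") & ident_ok
  refute[mis] <- TRUE; reason[mis] <- "misnamed_gene"

  events$status[has][refute] <- "refuted"
  events$reason[has][refute] <- reason[refute]
  events
}

#' Does a genome carry at least one confirmed rearrangement?
#'
#' @param events Screened event data.frame for one genome.
#' @return TRUE iff at least one event has status `confirmed`.
#' @export
genome_is_rearranged <- function(events) {
  nrow(events) > 0L && any(events$status == "confirmed")
}

#' Detect, classify and screen rearrangements for a set of architectures
#'
#' Convenience wrapper running [moved_gene_set()], [classify_events()] and
#' [screen_annotation_errors()] over a list of architectures.
#'
#' @param architectures Named list of `mito_arch` objects.
#' @param evidence Optional evidence data.frame.
#' @param identity_threshold Passed to [screen_annotation_errors()].
#' @return Combined screened event data.frame over all genomes.
#' @export
detect_rearrangements <- function(architectures, evidence = NULL,
                                  identity_threshold = 0.80) {
  evs <- lapply(architectures, function(a) classify_events(canonicalize(a)))
  events <- do.call(rbind, c(evs, list(.empty_events())))
  rownames(events) <- NULL
  screen_annotation_errors(events, evidence, identity_threshold)
}
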