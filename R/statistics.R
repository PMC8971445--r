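# Aggregation of screened events over taxonomy and genes: per-taxon and
# per-gene rearrangement proportions, summary tables, breakdowns, the
# order-by-gene proportion matrix and hotspot regions.

#' Round half-up to a fixed number of decimals
#'
#' Commercial rounding (0.5 always rounds away from zero), the convention
#' used for all reported percentages; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-taxon rearrangement proportion
#'
#' `PRo = NRo / (NE * 37) * 100`: the number of rearranged genes in a taxon
#' divided by the number of gene slots (37 per genome) across its `NE`
#' species, as a percentage rounded half-up to `digits` decimals.
#'
#' @param NRo Integer, number of rearranged genes over the taxon.
#' @param NE Integer, number of species in the taxon (>= 1).
#' @param digits Decimals in the reported percentage (default 2).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' proportion_taxon(6, 6)      # 2.70
#' proportion_taxon(751, 1259) # 1.61
proportion_taxon <- function(NRo, NE, digits = 2) {
  if (any(NE < 1)) stop("NE must be >= 1")
  if (any(NRo < 0)) stop("NRo must be >= 0")
  round_half_up(NRo / (NE * 37) * 100, digits)
}

#' Per-gene rearrangement proportion
#'
#' `PRg = NRg / NE * 100`: rearrangements of one gene within a taxon per
#' species, as a percentage. May exceed 100 when a gene has several events
#' per species (reported raw, with a warning).
#'
#' @param NRg Integer, number of rearrangements of the gene in the taxon.
#' @param NE Integer, number of species in the taxon (>= 1).
#' @param digits Decimals in the reported percentage (default 2).
#' @return Percentage (>= 0).
#' @export
#' @examples
#' proportion_gene(9, 37) # 24.32
proportion_gene <- function(NRg, NE, digits = 2) {
  if (any(NE < 1)) stop("NE must be >= 1")
  out <- round_half_up(NRg / NE * 100, digits)
  if (any(out > 100)) {
    warning("PRg exceeds 100: some genes have multiple events per species")
  }
  out
}

.selector_counts <- function(events, selector) {
  switch(selector,
    differing = events,
    confirmed = events[events$status == "confirmed", , drop = FALSE],
    stop("selector must be 'differing' or 'confirmed'")
  )
}

#' Summarize rearrangement events per taxon
#'
#' Aggregates screened events over the taxonomy at one rank, reproducing the
#' layout of a per-class (or per-order) summary table: per taxon the number
#' of orders and species, genes differing from the ancestral arrangement,
#' confirmed events split into duplications / deletions /
#' inversions-translocations, refuted events, and the rearrangement
#' percentage from [proportion_taxon()]. With the default
#' `selector = "differing"` the percentage uses confirmed + refuted counts;
#' `selector = "confirmed"` gives the post-curation rate.
#'
#' @param events Screened event data.frame covering all genomes.
#' @param taxonomy Taxonomy data.frame (see [read_taxonomy_tsv()]); every
#'   genome in `events` must appear.
#' @param rank `"class"` or `"order"`.
#' @param selector Which events feed the percentage: `"differing"` (default)
#'   or `"confirmed"`.
#' @param total_row Append a `Total` row summing all taxa?
#' @return Data.frame with columns `taxon`, `n_orders`, `n_species`,
#'   `genes_differing`, `n_confirmed`, `n_dup`, `n_del`, `n_inv_tra`,
#'   `n_refuted`, `pct_reorganization`.
#' @export
summarize_rearrangements <- function(events, taxonomy, rank = c("class", "order"),
                                     selector = c("differing", "confirmed"),
                                     total_row = TRUE) {
  rank <- match.arg(rank)
  selector <- match.arg(selector)
  missing_tax <- setdiff(unique(events$genome_id), taxonomy$genome_id)
  if (length(missing_tax) > 0L) {
    stop("missing taxonomy for genome(s): ", paste(missing_tax, collapse = ", "))
  }
  taxa <- unique(taxonomy[[rank]])
  ev_taxon <- taxonomy[[rank]][match(events$genome_id, taxonomy$genome_id)]

  one <- function(tx) {
    tsel <- taxonomy[[rank]] == tx
    e <- events[!is.na(ev_taxon) & ev_taxon == tx, , drop = FALSE]
    conf <- e[e$status == "confirmed", , drop = FALSE]
    n_species <- sum(tsel)
    nro <- nrow(.selector_counts(e, selector))
    data.frame(
      taxon = tx,
      n_orders = length(unique(taxonomy$order[tsel])),
      n_species = n_species,
      genes_differing = nrow(e),
      n_confirmed = nrow(conf),
      n_dup = sum(conf$reported_class == "dup"),
      n_del = sum(conf$reported_class == "del"),
      n_inv_tra = sum(conf$reported_class == "inv_tra"),
      n_refuted = sum(e$status == "refuted"),
      pct_reorganization = if (n_species >= 1) proportion_taxon(nro, n_species) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(taxa, one))
  if (total_row) {
    tot_nro <- nrow(.selector_counts(events, selector))
    total <- data.frame(
      taxon = "Total",
      n_orders = length(unique(taxonomy$order)),
      n_species = nrow(taxonomy),
      genes_differing = nrow(events),
      n_confirmed = sum(events$status == "confirmed"),
      n_dup = sum(events$reported_class == "dup" & events$status == "confirmed"),
      n_del = sum(events$reported_class == "del" & events$status == "confirmed"),
      n_inv_tra = sum(events$reported_class == "inv_tra" & events$status == "confirmed"),
      n_refuted = sum(events$status == "refuted"),
      pct_reorganization = proportion_taxon(tot_nro, max(1L, nrow(taxonomy))),
      stringsAsFactors = FALSE
    )
    out <- rbind(out, total)
  }
  rownames(out) <- NULL
  out
}

#' Breakdown of confirmed events by type and by gene category
#'
#' Fractions of confirmed events that are inversions/translocations,
#' duplications and deletions, and fractions by gene category (tRNA, rRNA,
#' protein), as percentages rounded half-up to one decimal, with
#' denominators reported.
#'
#' @param events Screened event data.frame.
#' @param digits Decimals in the percentages (default 1).
#' @return List with data.frames `by_class` (`reported_class`, `n`, `pct`)
#'   and `by_category` (`category`, `n`, `pct`), and `n_confirmed`. Empty
#'   data.frames when no event is confirmed.
#' @export
event_breakdown <- function(events, digits = 1) {
  conf <- events[events$status == "confirmed", , drop = FALSE]
  n <- nrow(conf)
  if (n == 0L) {
    return(list(
      by_class = data.frame(reported_class = character(), n = integer(),
                            pct = numeric(), stringsAsFactors = FALSE),
      by_category = data.frame(category = character(), n = integer(),
                               pct = numeric(), stringsAsFactors = FALSE),
      n_confirmed = 0L
    ))
  }
  classes <- c("inv_tra", "dup", "del")
  nc <- vapply(classes, function(k) sum(conf$reported_class == k), integer(1))
  cats <- c("tRNA", "rRNA", "protein")
  cat_of <- unname(.GENE_CATEGORY[conf$symbol])
  ncat <- vapply(cats, function(k) sum(cat_of == k), integer(1))
  list(
    by_class = data.frame(reported_class = classes, n = unname(nc),
                          pct = round_half_up(unname(nc) / n * 100, digits),
                          stringsAsFactors = FALSE),
    by_category = data.frame(category = cats, n = unname(ncat),
                             pct = round_half_up(unname(ncat) / n * 100, digits),
                             stringsAsFactors = FALSE),
    n_confirmed = n
  )
}

#' Per-gene rearrangement proportion matrix
#'
#' A matrix of per-gene rearrangement proportions (`PRg`): rows are the
#' taxonomic orders with at least one selected event (in taxonomy file
#' order), columns the 37 genes in ancestral order.
#'
#' @param events Screened event data.frame.
#' @param taxonomy Taxonomy data.frame.
#' @param selector `"confirmed"` (default; post-curation, Eq.-2 style) or
#'   `"differing"`.
#' @return Numeric matrix (percentages, 2 decimals) with dimnames.
#' @export
gene_matrix <- function(events, taxonomy, selector = c("confirmed", "differing")) {
  selector <- match.arg(selector)
  e <- .selector_counts(events, selector)
  ord <- taxonomy$order[match(e$genome_id, taxonomy$genome_id)]
  orders <- unique(taxonomy$order)
  orders <- orders[orders %in% ord]
  m <- matrix(0, nrow = length(orders), ncol = 37L,
              dimnames = list(orders, .ANCESTRAL_SYMBOLS))
  if (length(orders) == 0L) return(m)
  ne <- vapply(orders, function(o) sum(taxonomy$order == o), integer(1))
  counts <- table(factor(ord, levels = orders),
                  factor(e$symbol, levels = .ANCESTRAL_SYMBOLS))
  m[] <- round_half_up(as.matrix(counts) / ne * 100, 2)
  m
}

#' Per-gene confirmed-event totals
#'
#' @param events Screened event data.frame.
#' @return Named integer vector of length 37 (ancestral gene order) counting
#'   confirmed events per gene.
#' @export
gene_event_totals <- function(events) {
  conf <- events[events$status == "confirmed", , drop = FALSE]
  tab <- table(factor(conf$symbol, levels = .ANCESTRAL_SYMBOLS))
  out <- as.integer(tab)
  names(out) <- .ANCESTRAL_SYMBOLS
  out
}

#' Rearrangement hotspot regions
#'
#' Maximal circular runs of genes (in ancestral order) whose rearrangement
#' totals reach a threshold, with a minimum run length. Captures the
#' clustering of rearrangements around the replication origins.
#'
#' @param gene_totals Numeric vector of 37 per-gene totals, in ancestral
#'   order (see [gene_event_totals()]).
#' @param min_run Minimum number of consecutive genes (default 2).
#' @param threshold Minimum per-gene total for membership.
#' @return Data.frame with one row per region: `start_index`, `length`,
#'   `genes` (comma-separated, circular ancestral order), `min_count`,
#'   `max_count`.
#' @export
hotspot_regions <- function(gene_totals, min_run = 2, threshold) {
  if (length(gene_totals) != 37L) stop("gene_totals must have length 37")
  if (threshold < 0) stop("threshold must be >= 0")
  hot <- gene_totals >= threshold
  empty <- data.frame(start_index = integer(), length = integer(),
                      genes = character(), min_count = numeric(),
                      max_count = numeric(), stringsAsFactors = FALSE)
  if (!any(hot)) return(empty)
  if (all(hot)) {
    return(data.frame(start_index = 1L, length = 37L,
                      genes = paste(.ANCESTRAL_SYMBOLS, collapse = ","),
                      min_count = min(gene_totals),
                      max_count = max(gene_totals), stringsAsFactors = FALSE))
  }
  # rotate so position 1 is cold, then take linear runs
  cold <- which(!hot)[1L]
  rot <- c(cold:37L, seq_len(cold - 1L))
  r <- rle(hot[rot])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0L) return(empty)
  out <- lapply(keep, function(k) {
    pos <- rot[starts[k]:ends[k]]
    data.frame(start_index = pos[1L], length = length(pos),
               genes = paste(.ANCESTRAL_SYMBOLS[pos], collapse = ","),
               min_count = min(gene_totals[pos]),
               max_count = max(gene_totals[pos]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
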