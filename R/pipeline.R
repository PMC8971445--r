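# End-to-end orchestration: read inputs, run detection -> screening ->
# statistics -> convergence, write all report tables and a run manifest.

#' Run the full rearrangement-analysis pipeline
#'
#' Reads annotation, taxonomy and (optionally) evidence tables, builds one
#' architecture per genome, detects and classifies rearrangements against
#' the ancestral order, screens them against the evidence, aggregates
#' per-class and per-order summaries, event breakdowns, the order-by-gene
#' proportion matrix and hotspot regions, and detects convergent
#' arrangements. All outputs are written as UTF-8 tab-separated tables plus
#' a JSON manifest; the analysis path is fully deterministic, so re-running
#' with identical inputs gives byte-identical outputs.
#'
#' @param annotations Path to the annotations TSV, or an annotation
#'   data.frame.
#' @param taxonomy Path to the taxonomy TSV, or a data.frame.
#' @param evidence Optional path to the evidence TSV, or a data.frame.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param selector Percentage selector for summaries: `"differing"`
#'   (default) or `"confirmed"`.
#' @param identity_threshold Evidence identity threshold in (0, 1], default
#'   0.80.
#' @param rank Convergence grouping rank, `"order"` (default) or `"class"`.
#' @param mode Convergence mode, `"signature"` (default) or
#'   `"whole_architecture"`.
#' @param hotspot_threshold Per-gene confirmed-event count for hotspot
#'   membership (default 1).
#' @param hotspot_min_run Minimum hotspot run length (default 2).
#' @param dedupe_species Keep only the first genome per species name?
#' @return List with `events`, `summary_class`, `summary_order`,
#'   `breakdown`, `gene_matrix`, `hotspots`, `convergences`, `architectures`
#'   and `manifest`.
#' @export
run_pipeline <- function(annotations, taxonomy, evidence = NULL,
                         out_dir = NULL,
                         selector = c("differing", "confirmed"),
                         identity_threshold = 0.80,
                         rank = c("order", "class"),
                         mode = c("signature", "whole_architecture"),
                         hotspot_threshold = 1,
                         hotspot_min_run = 2,
                         dedupe_species = FALSE) {
  selector <- match.arg(selector)
  rank <- match.arg(rank)
  mode <- match.arg(mode)
  if (is.character(annotations)) annotations <- read_architecture_tsv(annotations)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy_tsv(taxonomy)
  if (is.character(evidence)) evidence <- read_evidence_tsv(evidence)

  if (dedupe_species) {
    keep <- !duplicated(taxonomy$species)
    taxonomy <- taxonomy[keep, , drop = FALSE]
    annotations <- annotations[annotations$genome_id %in% taxonomy$genome_id, ,
                               drop = FALSE]
  }
  missing_tax <- setdiff(unique(annotations$genome_id), taxonomy$genome_id)
  if (length(missing_tax) > 0L) {
    stop("genomes without taxonomy rows: ", paste(missing_tax, collapse = ", "))
  }

  archs <- build_architectures(annotations)
  events <- detect_rearrangements(archs, evidence, identity_threshold)
  summary_class <- summarize_rearrangements(events, taxonomy, "class", selector)
  summary_order <- summarize_rearrangements(events, taxonomy, "order", selector)
  breakdown <- event_breakdown(events)
  gm <- gene_matrix(events, taxonomy)
  hot <- hotspot_regions(gene_event_totals(events),
                         min_run = hotspot_min_run,
                         threshold = hotspot_threshold)
  conv <- find_convergences(archs, taxonomy, rank = rank, mode = mode,
                            events = events)

  manifest <- list(
    package = "mitorearr",
    version = as.character(utils::packageVersion("mitorearr")),
    n_genomes = length(archs),
    n_events = nrow(events),
    n_confirmed = sum(events$status == "confirmed"),
    n_refuted = sum(events$status == "refuted"),
    n_rearranged_genomes = sum(vapply(split(events, events$genome_id),
                                      genome_is_rearranged, logical(1))),
    n_convergence_groups = nrow(conv),
    parameters = list(selector = selector,
                      identity_threshold = identity_threshold,
                      rank = rank, mode = mode,
                      hotspot_threshold = hotspot_threshold,
                      hotspot_min_run = hotspot_min_run,
                      dedupe_species = dedupe_species)
  )

  out <- list(events = events, summary_class = summary_class,
              summary_order = summary_order, breakdown = breakdown,
              gene_matrix = gm, hotspots = hot, convergences = conv,
              architectures = archs, manifest = manifest)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    write_events_tsv(events, file.path(out_dir, "events.tsv"))
    wt(summary_class, "summary_class.tsv")
    wt(summary_order, "summary_order.tsv")
    wt(breakdown$by_class, "breakdown_class.tsv")
    wt(breakdown$by_category, "breakdown_category.tsv")
    gm_df <- data.frame(order = rownames(gm), gm, check.names = FALSE,
                        stringsAsFactors = FALSE)
    wt(gm_df, "gene_matrix.tsv")
    wt(hot, "hotspots.tsv")
    wt(conv, "convergences.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
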