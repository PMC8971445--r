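# Reading per-genome gene annotations (GenBank FEATURES subset and a TSV
# dialect), the taxonomy table and the evidence table; building architectures.

.ANNOT_COLS <- c("genome_id", "label", "feature_class", "start", "end",
                 "strand", "pseudo")

.empty_annotations <- function() {
  data.frame(genome_id = character(), label = character(),
             feature_class = character(), start = integer(), end = integer(),
             strand = character(), pseudo = logical(),
             stringsAsFactors = FALSE)
}

#' Read gene annotations from GenBank-format feature blocks
#'
#' Parses a minimal subset of the GenBank flat-file format: the LOCUS line
#' (genome id and length), and tRNA/rRNA/CDS features with plain,
#' `complement(...)` or origin-wrapping `join(a..b,c..d)` locations, with
#' `/gene`, `/product` and `/pseudo` qualifiers. `gene` features that overlap
#' a typed feature are merged into it (not duplicated); `gene` features with
#' no typed counterpart are kept with feature class `gene`. Everything else
#' (ORIGIN sequence, references, D-loop features...) is ignored here;
#' control-region elements are stripped later by [build_architecture()].
#'
#' @param path Path to a GenBank flat file (one or more LOCUS records) or a
#'   character vector of its lines.
#' @return A data.frame of annotations with columns `genome_id`, `label`,
#'   `feature_class`, `start`, `end`, `strand`, `pseudo`.
#' @export
read_feature_blocks <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  recs <- list()
  cur_id <- NA_character_
  in_features <- FALSE
  feat <- NULL
  saw_features <- FALSE

  flush_feat <- function(f) {
    if (is.null(f)) return()
    label <- if (!is.na(f$gene)) f$gene else f$product
    if (is.na(label)) {
      warning(sprintf("feature %s at %d..%d in %s has no /gene or /product qualifier; skipped",
                      f$class, f$start, f$end, f$genome_id))
      return()
    }
    recs[[length(recs) + 1L]] <<- data.frame(
      genome_id = f$genome_id, label = label, feature_class = f$class,
      start = f$start, end = f$end, strand = f$strand, pseudo = f$pseudo,
      stringsAsFactors = FALSE
    )
  }

  for (ln in lines) {
    if (grepl("^LOCUS", ln)) {
      flush_feat(feat); feat <- NULL
      cur_id <- strsplit(trimws(ln), "\\s+")[[1]][2]
      in_features <- FALSE
      next
    }
    if (grepl("^FEATURES", ln)) {
      in_features <- TRUE
      saw_features <- TRUE
      next
    }
    if (grepl("^(ORIGIN|CONTIG|//)", ln)) {
      flush_feat(feat); feat <- NULL
      in_features <- FALSE
      next
    }
    if (!in_features) next
    m <- regmatches(ln, regexec("^ {5}(\\S+)\\s+(.*)$", ln))[[1]]
    if (length(m) == 3L && !grepl("^\\s", substr(ln, 6, 6))) {
      # new feature line
      flush_feat(feat); feat <- NULL
      cls <- m[2]
      loc <- trimws(m[3])
      if (!cls %in% c("gene", "tRNA", "rRNA", "CDS")) next
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      wrap <- grepl("^join\\(", loc)
      if (wrap) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) < 2L) {
        stop(sprintf("malformed location string '%s' in %s", trimws(m[3]), cur_id))
      }
      start <- as.integer(nums[1]); end <- as.integer(nums[length(nums)])
      feat <- list(genome_id = cur_id, class = cls, start = start, end = end,
                   strand = strand, gene = NA_character_,
                   product = NA_character_, pseudo = FALSE)
    } else if (!is.null(feat)) {
      q <- trimws(ln)
      if (grepl("^/gene=", q)) {
        feat$gene <- gsub("\"", "", sub("^/gene=", "", q))
      } else if (grepl("^/product=", q)) {
        feat$product <- gsub("\"", "", sub("^/product=", "", q))
      } else if (q == "/pseudo" || grepl("^/pseudo$|^/pseudogene=", q)) {
        feat$pseudo <- TRUE
      }
    }
  }
  flush_feat(feat)

  if (!saw_features) {
    warning("no FEATURES section found")
    return(.empty_annotations())
  }
  if (length(recs) == 0L) return(.empty_annotations())
  ann <- do.call(rbind, recs)

  # merge bare 'gene' features into overlapping typed features
  keep <- rep(TRUE, nrow(ann))
  for (i in which(ann$feature_class == "gene")) {
    typed <- ann$feature_class != "gene" & ann$genome_id == ann$genome_id[i] &
      ann$start <= ann$end[i] & ann$end >= ann$start[i]
    if (any(typed)) keep[i] <- FALSE
  }
  ann <- ann[keep, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Read gene annotations from the TSV dialect
#'
#' The canonical fixture format emitted by [simulate_dataset()]: tab-separated
#' with header `genome_id, label, feature_class, start, end, strand, pseudo`.
#' Coordinates are 1-based inclusive; a feature may wrap the circular origin
#' (end < start).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of annotations (columns as in
#'   [read_feature_blocks()]).
#' @export
read_architecture_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!identical(names(tab), .ANNOT_COLS)) {
    stop(sprintf("bad annotation header: expected '%s', got '%s'",
                 paste(.ANNOT_COLS, collapse = ","),
                 paste(names(tab), collapse = ",")))
  }
  start <- suppressWarnings(as.integer(tab$start))
  end <- suppressWarnings(as.integer(tab$end))
  bad <- which(is.na(start) | is.na(end) | start < 1L | end < 1L)
  if (length(bad) > 0L) {
    stop(sprintf("non-integer or non-positive coordinates in row %d of %s",
                 bad[1], path))
  }
  bad <- which(!tab$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("strand must be '+' or '-' (row %d of %s has '%s')",
                 bad[1], path, tab$strand[bad[1]]))
  }
  data.frame(genome_id = tab$genome_id, label = tab$label,
             feature_class = tab$feature_class, start = start, end = end,
             strand = tab$strand,
             pseudo = tab$pseudo %in% c("TRUE", "true", "1"),
             stringsAsFactors = FALSE)
}

#' Write gene annotations in the TSV dialect
#' @param annotations Annotation data.frame (see [read_architecture_tsv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architecture_tsv <- function(annotations, path) {
  stopifnot(all(.ANNOT_COLS %in% names(annotations)))
  utils::write.table(annotations[, .ANNOT_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the taxonomy table
#'
#' Tab-separated, header `genome_id, species, class, order, family`
#' (optionally `suborder`). `genome_id` must be unique; class and order must
#' be non-empty.
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_taxonomy_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "species", "class", "order")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("taxonomy table missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$genome_id)) {
    stop("duplicated genome_id in taxonomy table")
  }
  if (any(!nzchar(tab$class)) || any(!nzchar(tab$order))) {
    stop("taxonomy class/order must be non-empty")
  }
  if (!"family" %in% names(tab)) tab$family <- NA_character_
  tab
}

#' Read the per-gene evidence table
#'
#' External sequence-verification results used by
#' [screen_annotation_errors()]: tab-separated with header `genome_id,
#' symbol, copy_index, verified_strand, identity_fraction, located`.
#' `verified_strand` is `+`, `-` or `unknown`; `identity_fraction` is in
#' \[0, 1\] (or empty); `located` is TRUE when the gene sequence was found in
#' the genome even if unannotated.
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
read_evidence_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "symbol", "copy_index", "verified_strand",
            "identity_fraction", "located")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("evidence table missing columns: ", paste(miss, collapse = ", "))
  }
  tab$copy_index <- as.integer(tab$copy_index)
  tab$identity_fraction <- suppressWarnings(as.numeric(tab$identity_fraction))
  ok <- is.na(tab$identity_fraction) |
    (tab$identity_fraction >= 0 & tab$identity_fraction <= 1)
  if (!all(ok)) stop("identity_fraction must lie in [0, 1]")
  if (!all(tab$verified_strand %in% c("+", "-", "unknown"))) {
    stop("verified_strand must be '+', '-' or 'unknown'")
  }
  tab$located <- tab$located %in% c("TRUE", "true", "1", TRUE)
  tab
}

#' Write a rearrangement-event table
#' @param events Event data.frame from [classify_events()] /
#'   [screen_annotation_errors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  cols <- c("genome_id", "symbol", "copy_index", "kind", "reported_class",
            "status", "reason")
  utils::write.table(events[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Resolve bare leucine/serine tRNA labels from neighbour context after
# sorting by coordinate: nad1-adjacent -> trnL1, nad5-adjacent -> trnL2,
# trnH-adjacent -> trnS1, trnD-adjacent -> trnS2.
.resolve_ambiguous <- function(symbols, ambiguous_idx, squashed) {
  n <- length(symbols)
  for (i in ambiguous_idx) {
    prv <- symbols[if (i == 1L) n else i - 1L]
    nxt <- symbols[if (i == n) 1L else i + 1L]
    is_leu <- grepl("l", squashed[i])
    if (is_leu) {
      if (identical(prv, "rrnL") || identical(nxt, "nad1")) {
        symbols[i] <- "trnL1"
      } else if (identical(prv, "trnS1") || identical(nxt, "nad5") ||
                 identical(prv, "nad5") || identical(nxt, "nad5")) {
        symbols[i] <- "trnL2"
      }
    } else {
      if (identical(prv, "trnH") || identical(nxt, "trnH") ||
          identical(nxt, "trnL2")) {
        symbols[i] <- "trnS1"
      } else if (identical(prv, "trnD") || identical(nxt, "trnD") ||
                 identical(prv, "cox1")) {
        symbols[i] <- "trnS2"
      }
    }
  }
  symbols
}

#' Build a genome architecture from annotation records
#'
#' Normalizes labels to the canonical vocabulary, strips control-region/OL
#' features, sorts features by start coordinate around the circle (ties by
#' end, then symbol), assigns copy indices in coordinate order for repeated
#' symbols, and canonicalizes the rotation. Bare leucine/serine tRNA labels
#' are resolved from their sorted neighbours (nad1-adjacent trnL1,
#' nad5-adjacent trnL2, trnH-adjacent trnS1, trnD-adjacent trnS2); if the
#' context matches neither, the feature is flagged ambiguous and excluded.
#' Features whose label cannot be mapped are excluded and reported in the
#' `unmapped` attribute (and as a warning), never silently renamed.
#'
#' @param annotations Annotation data.frame for a single genome.
#' @param circular Logical, genome circularity (origin-wrapping features are
#'   positioned by their start).
#' @return A canonicalized `mito_arch`, with attribute `unmapped` (data.frame
#'   of excluded rows, if any).
#' @export
build_architecture <- function(annotations, circular = TRUE) {
  if (nrow(annotations) == 0L) stop("zero mappable genes")
  ids <- unique(annotations$genome_id)
  if (length(ids) != 1L) {
    stop("annotations must share one genome_id; got: ",
         paste(ids, collapse = ", "))
  }
  ann <- annotations
  ann <- ann[!is_noncoding_label(ann$label), , drop = FALSE]
  if (nrow(ann) == 0L) stop("zero mappable genes")
  ann <- ann[order(ann$start, ann$end, ann$label), , drop = FALSE]

  squashed <- .squash_label(ann$label)
  symbols <- rep(NA_character_, nrow(ann))
  ambiguous <- integer(0)
  for (i in seq_len(nrow(ann))) {
    res <- tryCatch(
      normalize_gene_symbol(ann$label[i], ann$feature_class[i]),
      mitorearr_ambiguous_symbol = function(e) "ambiguous",
      mitorearr_unmapped_label = function(e) NA_character_
    )
    if (identical(res, "ambiguous")) ambiguous <- c(ambiguous, i) else symbols[i] <- res
  }
  if (length(ambiguous) > 0L) {
    symbols[ambiguous] <- "?"
    symbols <- .resolve_ambiguous(symbols, ambiguous, squashed)
    symbols[symbols == "?"] <- NA_character_
  }

  dropped <- ann[is.na(symbols), , drop = FALSE]
  if (nrow(dropped) > 0L) {
    warning(sprintf("genome %s: %d feature(s) with unmapped or unresolvable labels excluded: %s",
                    ids, nrow(dropped),
                    paste(unique(dropped$label), collapse = ", ")))
  }
  keep <- !is.na(symbols)
  ann <- ann[keep, , drop = FALSE]
  symbols <- symbols[keep]
  if (nrow(ann) == 0L) stop("zero mappable genes")

  arch <- architecture(
    ids, symbols, ifelse(ann$strand == "+", 1L, -1L),
    pseudo = ann$pseudo, circular = circular,
    source_length_bp = suppressWarnings(max(ann$end))
  )
  arch <- canonicalize(arch)
  attr(arch, "unmapped") <- dropped
  arch
}

#' Build one architecture per genome from a combined annotation table
#'
#' @param annotations Annotation data.frame possibly covering many genomes.
#' @param circular Logical, genome circularity.
#' @return Named list of `mito_arch` objects (names = genome ids, in order of
#'   first appearance).
#' @export
build_architectures <- function(annotations, circular = TRUE) {
  ids <- unique(annotations$genome_id)
  out <- lapply(ids, function(id) {
    build_architecture(annotations[annotations$genome_id == id, , drop = FALSE],
                       circular = circular)
  })
  names(out) <- ids
  out
}
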