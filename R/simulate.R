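# Synthetic mitogenome generator: taxonomies, genomes evolved from the
# ancestral order by stochastic rearrangement events, injected annotation
# errors with matching evidence, and ground-truth logs.

#' Simulation configuration
#'
#' Bundles all generator parameters. Defaults emulate the statistical
#' structure of curated vertebrate mitogenome sets: about 36% of genomes
#' carry at least one rearrangement, small rearranged blocks (1-3 genes),
#' event kinds dominated by transpositions/inversions over duplications and
#' (rare) deletions, and a low per-gene annotation-error rate.
#'
#' @param seed Top-level RNG seed; per-genome substreams are derived from it
#'   so results are stable under dataset resizing.
#' @param n_classes,orders_per_class,species_per_order Taxonomy shape.
#' @param rearranged_fraction Probability that a genome carries at least one
#'   rearrangement event (default 0.36).
#' @param event_probs Named sampling probabilities over event kinds
#'   (transposition, inversion, reverse_transposition, tdrl, duplication,
#'   deletion); must sum to 1.
#' @param events_geom_p,max_events Events per rearranged genome follow a
#'   geometric distribution with success probability `events_geom_p`,
#'   truncated at `max_events`.
#' @param block_len_probs Probabilities for block lengths 1, 2, 3, ...
#' @param pseudo_dup_prob Probability that a duplicated copy is annotated as
#'   a pseudogene.
#' @param error_rate Per-genome expected fraction of gene loci receiving an
#'   injected annotation error (default 0.004 per locus).
#' @param error_probs Named probabilities over error types (`strand_flip`,
#'   `name_swap`, `omission`).
#' @param plant_convergence Plant the same rearrangement in one genome of
#'   each of the first two taxonomic orders?
#' @param synonym_labels Emit GenBank-style synonym labels (tRNA-Phe, ND1,
#'   COX1, ...) instead of canonical symbols?
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_classes = 4L,
                              orders_per_class = 3L,
                              species_per_order = 10L,
                              rearranged_fraction = 0.36,
                              event_probs = c(transposition = 0.35,
                                              inversion = 0.20,
                                              reverse_transposition = 0.15,
                                              tdrl = 0.17,
                                              duplication = 0.11,
                                              deletion = 0.02),
                              events_geom_p = 0.6,
                              max_events = 5L,
                              block_len_probs = c(0.5, 0.3, 0.2),
                              pseudo_dup_prob = 0.15,
                              error_rate = 0.004,
                              error_probs = c(strand_flip = 0.6,
                                              name_swap = 0.3,
                                              omission = 0.1),
                              plant_convergence = FALSE,
                              synonym_labels = FALSE) {
  stopifnot(abs(sum(event_probs) - 1) < 1e-8,
            abs(sum(error_probs) - 1) < 1e-8,
            rearranged_fraction >= 0, rearranged_fraction <= 1,
            error_rate >= 0, error_rate <= 1,
            n_classes >= 1, orders_per_class >= 1, species_per_order >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Apply one rearrangement event to an architecture
#'
#' Deterministic event application. An inversion flips the order and all
#' signs of a block; a transposition moves a block; a reverse transposition
#' moves and flips it; a TDRL duplicates a block in tandem and then deletes
#' one copy of each gene according to a kept-copy pattern (optionally
#' retaining both copies of designated genes); a duplication inserts a
#' tandem copy of one gene occurrence; a deletion removes one occurrence.
#' Copy indices are renumbered in list order afterwards.
#'
#' @param arch A `mito_arch`.
#' @param spec Event specification: a list with `kind` and parameters
#'   `start` (1-based position of the block in the current circular gene
#'   list), `len` (block length), `dest` (insertion point in the remaining
#'   list, 0..n-len, for transpositions), `keep_first` (logical vector over
#'   the block for TDRL: keep the first-copy occurrence?), `retain_both`
#'   (integer positions within the block kept in both copies), `pseudo`
#'   (duplicated copy is a pseudogene).
#' @return The rearranged `mito_arch`.
#' @export
#' @examples
#' flipQ <- list(kind = "inversion", start = 8, len = 1)
#' apply_event(ancestral_order(), flipQ)$genes[8, ]
apply_event <- function(arch, spec) {
  stopifnot(inherits(arch, "mito_arch"), is.list(spec))
  g <- arch$genes
  n <- nrow(g)
  kind <- spec$kind
  renumber <- function(df) {
    df$copy_index <- stats::ave(seq_len(nrow(df)), df$symbol, FUN = seq_along)
    rownames(df) <- NULL
    df
  }
  flip <- function(df) {
    df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
    df$sign <- -df$sign
    df
  }
  if (kind %in% c("duplication", "deletion")) {
    pos <- spec$start
    if (is.null(pos) || pos < 1L || pos > n) stop("invalid gene position")
    if (kind == "deletion") {
      if (n == 1L) stop("cannot delete the last gene")
      g <- g[-pos, , drop = FALSE]
    } else {
      copy <- g[pos, , drop = FALSE]
      copy$pseudo <- isTRUE(spec$pseudo)
      g <- rbind(g[seq_len(pos), , drop = FALSE], copy,
                 if (pos < n) g[(pos + 1L):n, , drop = FALSE])
    }
    arch$genes <- renumber(g)
    return(arch)
  }

  len <- spec$len
  if (is.null(len) || len < 1L || len >= n) stop("invalid block bounds")
  bp <- ((spec$start - 1L + 0:(len - 1L)) %% n) + 1L
  block <- g[bp, , drop = FALSE]
  rest <- g[-bp, , drop = FALSE]
  m <- nrow(rest)

  if (kind == "inversion") {
    g[bp, ] <- flip(block)
    arch$genes <- renumber(g)
    return(arch)
  }
  if (kind %in% c("transposition", "reverse_transposition")) {
    dest <- spec$dest
    if (is.null(dest) || dest < 0L || dest > m) stop("invalid insertion point")
    if (kind == "reverse_transposition") block <- flip(block)
    g2 <- rbind(
      if (dest > 0L) rest[seq_len(dest), , drop = FALSE],
      block,
      if (dest < m) rest[(dest + 1L):m, , drop = FALSE]
    )
    arch$genes <- renumber(g2)
    return(arch)
  }
  if (kind == "tdrl") {
    if (len < 2L) stop("TDRL blocks need length >= 2")
    keep1 <- rep_len(as.logical(spec$keep_first), len)
    retain <- spec$retain_both
    if (is.null(retain)) retain <- integer(0)
    first_rows <- which(keep1 | seq_len(len) %in% retain)
    second_rows <- which(!keep1 | seq_len(len) %in% retain)
    new_block <- rbind(block[first_rows, , drop = FALSE],
                       block[second_rows, , drop = FALSE])
    # keep original relative order of the rest, starting after the block end
    after <- ((bp[len] + seq_len(n)) - 1L) %% n + 1L
    after <- after[!after %in% bp]
    g2 <- rbind(new_block, g[after, , drop = FALSE])
    arch$genes <- renumber(g2)
    return(arch)
  }
  stop("unknown event kind: ", kind)
}

# Sample one random event spec valid for an architecture of size n.
.random_event_spec <- function(n, config) {
  kind <- sample(names(config$event_probs), 1L, prob = config$event_probs)
  lens <- seq_along(config$block_len_probs)
  len <- sample(lens, 1L, prob = config$block_len_probs)
  len <- min(len, n - 1L)
  if (kind %in% c("duplication", "deletion")) {
    return(list(kind = kind, start = sample.int(n, 1L),
                pseudo = kind == "duplication" &&
                  stats::runif(1) < config$pseudo_dup_prob))
  }
  if (kind == "tdrl") {
    len <- max(2L, len)
    start <- sample.int(n, 1L)
    repeat {
      keep1 <- stats::runif(len) < 0.5
      # identity patterns: all kept-first genes form a prefix of the block
      if (!all(diff(keep1) <= 0)) break
    }
    return(list(kind = kind, start = start, len = len, keep_first = keep1))
  }
  start <- sample.int(n, 1L)
  m <- n - len
  if (m < 2L) {
    return(list(kind = "inversion", start = start, len = len))
  }
  p0 <- if (start + len - 1L > n) m else start - 1L  # original gap position
  if (kind == "transposition") {
    dest <- sample(setdiff(0:m, p0), 1L)     # excludes the identity move
  } else {
    dest <- sample.int(m + 1L, 1L) - 1L      # 0..m (flip always changes it)
  }
  list(kind = kind, start = start, len = len, dest = dest)
}

# Rest-list position of a block's original gap (the slot it was cut from).
.block_gap <- function(start, len, n) {
  if (start + len - 1L > n) n - len else start - 1L
}

# Ancestral-index set disturbed by an event, for safe error placement:
# the block genes plus, for transpositions, the jumped-over span.
.touched_indices <- function(arch_before, spec) {
  g <- arch_before$genes
  n <- nrow(g)
  if (spec$kind %in% c("duplication", "deletion")) {
    return(unname(.ANCESTRAL_INDEX[g$symbol[spec$start]]))
  }
  bp <- ((spec$start - 1L + 0:(spec$len - 1L)) %% n) + 1L
  syms <- g$symbol[bp]
  extra <- character(0)
  if (spec$kind %in% c("transposition", "reverse_transposition")) {
    rest <- g$symbol[-bp]
    m <- length(rest)
    dest <- spec$dest
    p0 <- .block_gap(spec$start, spec$len, n)
    # segment jumped over by the block, and its circular complement: either
    # can end up marked as moved when it is no longer than the block
    seg <- if (dest > p0) rest[(p0 + 1L):dest] else if (dest < p0)
      rest[(dest + 1L):p0] else character(0)
    comp <- setdiff(rest, seg)
    if (length(seg) <= spec$len + 1L) extra <- c(extra, seg)
    if (length(comp) <= spec$len + 1L) extra <- c(extra, comp)
    # neighbours of the insertion point
    nb <- c(if (dest >= 1L) rest[dest], if (dest < m) rest[dest + 1L])
    extra <- c(extra, nb)
  }
  unname(.ANCESTRAL_INDEX[unique(c(syms, extra))])
}

# Expected per-kind event counts for a single-event genome, derived
# combinatorially from the spec (independent of the detection DP).
.expected_single_event <- function(spec, n) {
  counts <- c(duplication = 0L, deletion = 0L, inversion = 0L,
              translocation = 0L)
  k <- spec$kind
  if (k == "duplication") counts["duplication"] <- 1L
  else if (k == "deletion") counts["deletion"] <- 1L
  else if (k == "inversion") counts["inversion"] <- spec$len
  else if (k == "reverse_transposition") counts["inversion"] <- spec$len
  else if (k == "transposition") {
    m <- n - spec$len
    jump <- abs(spec$dest - .block_gap(spec$start, spec$len, n))
    counts["translocation"] <- min(spec$len, jump, m - jump)
  } else if (k == "tdrl") {
    len <- spec$len
    s1 <- which(spec$keep_first)
    s2 <- which(!spec$keep_first)
    best <- max(vapply(0:len, function(t) {
      sum(s1 <= t) + sum(s2 > t)
    }, integer(1)))
    counts["translocation"] <- len - best
  }
  counts
}

#' Simulate one genome
#'
#' With probability `1 - rearranged_fraction` returns the ancestral
#' architecture with an empty truth log; otherwise draws a truncated
#' geometric number of events, applies them sequentially and records them.
#' Draws are rejected (and redrawn) if the resulting non-pseudo architecture
#' is circularly identical to the ancestral one, so "rearranged" always
#' means a genuinely derived architecture.
#'
#' @param config A `sim_config`.
#' @param genome_id Genome identifier.
#' @param genome_index Integer used to derive the per-genome RNG substream.
#' @return List with `arch` (a `mito_arch`) and `truth` (genome_id, events,
#'   touched ancestral indices, expected single-event kind counts, errors
#'   placeholder).
#' @export
simulate_genome <- function(config, genome_id, genome_index = 1L) {
  s <- (as.numeric(config$seed) * 1009 + as.numeric(genome_index) * 9176 + 1) %%
    2147483629
  set.seed(as.integer(s))
  truth <- list(genome_id = genome_id, rearranged = FALSE, events = list(),
                touched = integer(0), expected_counts = NULL,
                errors = data.frame(symbol = character(),
                                    copy_index = integer(),
                                    error_type = character(),
                                    stringsAsFactors = FALSE))
  if (stats::runif(1) >= config$rearranged_fraction) {
    return(list(arch = ancestral_order(genome_id), truth = truth))
  }
  anc_key_np <- ancestral_key()
  for (try in 1:25) {
    k <- min(stats::rgeom(1, config$events_geom_p) + 1L, config$max_events)
    arch <- ancestral_order(genome_id)
    events <- vector("list", k)
    touched <- integer(0)
    ok <- TRUE
    for (i in seq_len(k)) {
      spec <- .random_event_spec(nrow(arch$genes), config)
      touched <- union(touched, .touched_indices(arch, spec))
      arch2 <- tryCatch(apply_event(arch, spec), error = function(e) NULL)
      if (is.null(arch2)) { ok <- FALSE; break }
      events[[i]] <- spec
      arch <- arch2
    }
    if (!ok) next
    np <- arch
    np$genes <- np$genes[!np$genes$pseudo, , drop = FALSE]
    if (nrow(np$genes) == 0L) next
    if (architecture_key(np) == anc_key_np) next
    truth$rearranged <- TRUE
    truth$events <- events
    truth$touched <- touched
    if (k == 1L) {
      truth$expected_counts <- .expected_single_event(events[[1L]], 37L)
    }
    return(list(arch = canonicalize(arch), truth = truth))
  }
  # extraordinarily unlikely; fall back to an unrearranged genome
  list(arch = ancestral_order(genome_id), truth = truth)
}

# Typical gene lengths (bp) used to synthesize plausible coordinates.
.GENE_LENGTHS <- local({
  len <- rep(70L, 37L)
  names(len) <- .ANCESTRAL_SYMBOLS
  len[c("rrnS", "rrnL")] <- c(950L, 1560L)
  prot <- c(nad1 = 960L, nad2 = 1040L, cox1 = 1545L, cox2 = 684L,
            atp8 = 165L, atp6 = 680L, cox3 = 785L, nad3 = 350L,
            nad4L = 295L, nad4 = 1380L, nad5 = 1815L, nad6 = 525L,
            cob = 1140L)
  len[names(prot)] <- prot
  len
})

.SYNONYM_LABELS <- local({
  lab <- paste0("tRNA-", c(trnF = "Phe", trnV = "Val", trnI = "Ile",
                           trnQ = "Gln", trnM = "Met", trnW = "Trp",
                           trnA = "Ala", trnN = "Asn", trnC = "Cys",
                           trnY = "Tyr", trnD = "Asp", trnK = "Lys",
                           trnG = "Gly", trnR = "Arg", trnH = "His",
                           trnE = "Glu", trnT = "Thr", trnP = "Pro"))
  names(lab) <- c("trnF", "trnV", "trnI", "trnQ", "trnM", "trnW", "trnA",
                  "trnN", "trnC", "trnY", "trnD", "trnK", "trnG", "trnR",
                  "trnH", "trnE", "trnT", "trnP")
  lab <- c(lab,
           trnL1 = "tRNA-Leu(UUR)", trnL2 = "tRNA-Leu(CUN)",
           trnS1 = "tRNA-Ser(AGY)", trnS2 = "tRNA-Ser(UCN)",
           rrnS = "12S ribosomal RNA", rrnL = "16S ribosomal RNA",
           nad1 = "ND1", nad2 = "ND2", nad3 = "ND3", nad4 = "ND4",
           nad4L = "ND4L", nad5 = "ND5", nad6 = "ND6",
           cox1 = "COX1", cox2 = "COX2", cox3 = "COX3",
           atp6 = "ATPase 6", atp8 = "ATPase 8", cob = "CYTB")
  lab
})

#' Emit annotation rows for an architecture
#'
#' Synthesizes plausible 1-based coordinates from typical gene lengths (with
#' 1-bp spacers), a trailing control-region (D-loop) feature, and strand
#' characters from the signs. The row order follows the architecture's gene
#' list, so rebuilding from these rows reproduces the architecture.
#'
#' @param arch A `mito_arch`.
#' @param synonym_labels Emit GenBank-style synonyms instead of canonical
#'   symbols?
#' @return Annotation data.frame in the TSV dialect.
#' @export
annotations_from_architecture <- function(arch, synonym_labels = FALSE) {
  g <- arch$genes
  lens <- unname(.GENE_LENGTHS[g$symbol])
  start <- cumsum(c(1L, lens[-length(lens)] + 1L))
  end <- start + lens - 1L
  label <- if (synonym_labels) unname(.SYNONYM_LABELS[g$symbol]) else g$symbol
  cls <- unname(c(tRNA = "tRNA", rRNA = "rRNA", protein = "CDS")[
    .GENE_CATEGORY[g$symbol]])
  ann <- data.frame(
    genome_id = arch$genome_id, label = label, feature_class = cls,
    start = start, end = end, strand = ifelse(g$sign > 0, "+", "-"),
    pseudo = g$pseudo, stringsAsFactors = FALSE
  )
  dloop <- data.frame(genome_id = arch$genome_id, label = "D-loop",
                      feature_class = "gene", start = max(end) + 2L,
                      end = max(end) + 901L, strand = "+", pseudo = FALSE,
                      stringsAsFactors = FALSE)
  rbind(ann, dloop)
}

#' Inject annotation errors into a genome's annotation rows
#'
#' Selects gene loci far from any truly rearranged region (circular
#' ancestral-index distance >= 4 from every touched locus and from other
#' injected errors) and corrupts the annotation: a strand flip (the sequence
#' keeps its true strand; the evidence records it with identity 1.0), a
#' gene-name swap between two loci on the same ancestral strand at index
#' distance >= 3 (evidence reports full identity to the gene expected at
#' each locus), or an omission of a present gene (evidence has
#' `located = TRUE`). The truth log is updated so the expected refuted set
#' after screening is exact. Uses the current RNG state.
#'
#' @param annotations Annotation rows from [annotations_from_architecture()]
#'   (true, uncorrupted).
#' @param arch The true `mito_arch`.
#' @param truth The genome's truth log ([simulate_genome()]).
#' @param rate Per-locus error probability.
#' @param error_probs Named probabilities over `strand_flip`, `name_swap`,
#'   `omission`.
#' @return List with `annotations` (possibly corrupted), `evidence`
#'   (data.frame of evidence rows, possibly empty) and `truth` (updated).
#' @export
inject_annotation_errors <- function(annotations, arch, truth,
                                     rate = 0.004,
                                     error_probs = c(strand_flip = 0.6,
                                                     name_swap = 0.3,
                                                     omission = 0.1)) {
  stopifnot(rate >= 0, rate <= 1)
  evidence <- data.frame(genome_id = character(), symbol = character(),
                         copy_index = integer(), verified_strand = character(),
                         identity_fraction = numeric(), located = logical(),
                         stringsAsFactors = FALSE)
  n_err <- stats::rbinom(1L, 37L, rate)
  if (n_err == 0L) {
    return(list(annotations = annotations, evidence = evidence, truth = truth))
  }
  g <- arch$genes[!arch$genes$pseudo, , drop = FALSE]
  single <- names(which(table(g$symbol) == 1L))
  idx_of <- .ANCESTRAL_INDEX
  circ_dist <- function(i, j) pmin((i - j) %% 37L, (j - i) %% 37L)
  safe <- vapply(single, function(s) {
    i <- idx_of[[s]]
    row <- g[g$symbol == s, ]
    row$sign == .ANCESTRAL_SIGNS[[s]] &&
      (length(truth$touched) == 0L || all(circ_dist(i, truth$touched) >= 4L))
  }, logical(1))
  pool <- single[safe]

  used <- integer(0)
  pick_locus <- function() {
    ok <- pool[vapply(pool, function(s) {
      length(used) == 0L || all(circ_dist(idx_of[[s]], used) >= 4L)
    }, logical(1))]
    if (length(ok) == 0L) return(NA_character_)
    s <- if (length(ok) == 1L) ok else sample(ok, 1L)
    used <<- c(used, idx_of[[s]])
    pool <<- setdiff(pool, s)
    s
  }
  anc_strand <- function(s) if (.ANCESTRAL_SIGNS[[s]] > 0) "+" else "-"
  ann_row <- function(s) which(annotations$label == s &
                                 annotations$feature_class != "gene")[1L]

  add_error <- function(symbol, type) {
    truth$errors <<- rbind(truth$errors, data.frame(
      symbol = symbol, copy_index = 1L, error_type = type,
      stringsAsFactors = FALSE))
    evidence <<- rbind(evidence, data.frame(
      genome_id = arch$genome_id, symbol = symbol, copy_index = 1L,
      verified_strand = anc_strand(symbol), identity_fraction = 1.0,
      located = TRUE, stringsAsFactors = FALSE))
  }

  for (e in seq_len(n_err)) {
    type <- sample(names(error_probs), 1L, prob = error_probs)
    if (type == "name_swap") {
      a <- pick_locus()
      if (is.na(a)) break
      partners <- pool[vapply(pool, function(s) {
        .ANCESTRAL_SIGNS[[s]] == .ANCESTRAL_SIGNS[[a]] &&
          circ_dist(idx_of[[s]], idx_of[[a]]) >= 3L &&
          all(circ_dist(idx_of[[s]], used) >= 4L)
      }, logical(1))]
      if (length(partners) == 0L) next
      b <- if (length(partners) == 1L) partners else sample(partners, 1L)
      used <- c(used, idx_of[[b]])
      pool <- setdiff(pool, b)
      ra <- ann_row(a); rb <- ann_row(b)
      la <- annotations$label[ra]
      annotations$label[ra] <- annotations$label[rb]
      annotations$label[rb] <- la
      add_error(a, "name_swap"); add_error(b, "name_swap")
    } else {
      s <- pick_locus()
      if (is.na(s)) break
      r <- ann_row(s)
      if (type == "strand_flip") {
        annotations$strand[r] <- if (annotations$strand[r] == "+") "-" else "+"
        add_error(s, "strand_flip")
      } else {
        annotations <- annotations[-r, , drop = FALSE]
        add_error(s, "omission")
      }
    }
  }
  rownames(annotations) <- NULL
  list(annotations = annotations, evidence = evidence, truth = truth)
}

#' Simulate a complete dataset
#'
#' Generates a hierarchical taxonomy, one genome per species via
#' [simulate_genome()], annotation rows with injected errors and matching
#' evidence, and the truth log. Optionally plants one convergence: the same
#' event (a trnS1 transposition past trnH) applied to the first genome of
#' each of the first two taxonomic orders.
#'
#' @param config A `sim_config`.
#' @param out_dir Optional directory; when given, writes `annotations.tsv`,
#'   `taxonomy.tsv`, `evidence.tsv` and `truth.json` there.
#' @return (Invisibly when writing) a list with `annotations`, `taxonomy`,
#'   `evidence`, `truth` (per-genome list), `architectures` (true, named
#'   list) and `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_classes * config$orders_per_class * config$species_per_order
  cls <- rep(paste0("Class_", LETTERS[seq_len(config$n_classes)]),
             each = config$orders_per_class * config$species_per_order)
  ord <- rep(paste0("Order_",
                    rep(LETTERS[seq_len(config$n_classes)],
                        each = config$orders_per_class),
                    rep(seq_len(config$orders_per_class),
                        times = config$n_classes)),
             each = config$species_per_order)
  gid <- sprintf("G%05d", seq_len(n))
  taxonomy <- data.frame(
    genome_id = gid, species = sprintf("Species_%05d", seq_len(n)),
    class = cls, order = ord,
    family = paste0(ord, "_fam", ((seq_len(n) - 1L) %/% 5L) %% 2L + 1L),
    stringsAsFactors = FALSE
  )

  planted_ids <- character(0)
  planted_spec <- list(kind = "transposition", start = 30L, len = 1L,
                       dest = 28L)  # trnS1 moved before trnH
  if (isTRUE(config$plant_convergence) && config$orders_per_class >= 2L) {
    orders <- unique(taxonomy$order)
    planted_ids <- vapply(orders[1:2], function(o) {
      taxonomy$genome_id[taxonomy$order == o][1L]
    }, character(1))
  }

  ann_list <- vector("list", n)
  ev_list <- vector("list", n)
  truths <- vector("list", n)
  archs <- vector("list", n)
  for (i in seq_len(n)) {
    if (gid[i] %in% planted_ids) {
      arch <- canonicalize(apply_event(ancestral_order(gid[i]), planted_spec))
      truth <- list(genome_id = gid[i], rearranged = TRUE,
                    events = list(planted_spec),
                    touched = .touched_indices(ancestral_order(gid[i]),
                                               planted_spec),
                    expected_counts = .expected_single_event(planted_spec, 37L),
                    planted = TRUE,
                    errors = data.frame(symbol = character(),
                                        copy_index = integer(),
                                        error_type = character(),
                                        stringsAsFactors = FALSE))
      s <- (as.numeric(config$seed) * 1009 + as.numeric(i) * 9176 + 1) %%
        2147483629
      set.seed(as.integer(s))
    } else {
      sim <- simulate_genome(config, gid[i], genome_index = i)
      arch <- sim$arch
      truth <- sim$truth
      truth$planted <- FALSE
    }
    ann <- annotations_from_architecture(arch, synonym_labels = FALSE)
    inj <- inject_annotation_errors(ann, arch, truth,
                                    rate = config$error_rate,
                                    error_probs = config$error_probs)
    if (isTRUE(config$synonym_labels)) {
      lab <- inj$annotations$label
      hit <- lab %in% names(.SYNONYM_LABELS)
      lab[hit] <- unname(.SYNONYM_LABELS[lab[hit]])
      inj$annotations$label <- lab
    }
    ann_list[[i]] <- inj$annotations
    ev_list[[i]] <- inj$evidence
    truths[[i]] <- inj$truth
    archs[[i]] <- arch
  }
  names(archs) <- gid
  names(truths) <- gid
  out <- list(
    annotations = do.call(rbind, ann_list),
    taxonomy = taxonomy,
    evidence = do.call(rbind, ev_list),
    truth = truths,
    architectures = archs,
    config = config,
    planted_ids = planted_ids
  )
  rownames(out$annotations) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_architecture_tsv(out$annotations, file.path(out_dir, "annotations.tsv"))
    utils::write.table(out$taxonomy, file.path(out_dir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$evidence, file.path(out_dir, "evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(truths, function(t) t[c("genome_id", "rearranged", "events",
                                     "errors", "planted")]),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
    return(invisible(out))
  }
  out
}

#' Replay a truth log
#'
#' Folds [apply_event()] over a recorded event list starting from the
#' ancestral order; by construction this reproduces the emitted
#' architecture exactly.
#'
#' @param events List of event specs.
#' @param genome_id Identifier for the replayed architecture.
#' @return A canonicalized `mito_arch`.
#' @export
replay_events <- function(events, genome_id = "replay") {
  arch <- ancestral_order(genome_id)
  for (spec in events) arch <- apply_event(arch, spec)
  canonicalize(arch)
}
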