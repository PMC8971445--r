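# Convergent gene arrangements across taxa: canonical architecture keys,
# local rearrangement signatures, and breakpoint / inversion distances
# between signed permutations.

#' Canonical architecture key
#'
#' Deterministic serialization of a canonicalized architecture: the anchored
#' gene list with strand signs, copy markers and pseudogene flags. Two
#' genomes get equal keys iff their canonical architectures are identical
#' (rotation-invariant via [canonicalize()]).
#'
#' @param arch A `mito_arch`.
#' @return Character scalar.
#' @export
#' @examples
#' architecture_key(ancestral_order()) == ancestral_key()
architecture_key <- function(arch) {
  stopifnot(inherits(arch, "mito_arch"))
  arch <- canonicalize(arch)
  paste(.arch_tokens(arch$genes), collapse = "|")
}

#' The key of the ancestral architecture
#' @return Character scalar.
#' @export
ancestral_key <- function() {
  architecture_key(ancestral_order())
}

#' Local rearrangement signature of a genome
#'
#' The set of shared, comparable elements describing how a genome deviates
#' from the ancestral order: one element per maximal circular run of moved
#' genes (its observed signed order, confirmed events only), plus one
#' element per confirmed duplication or deletion naming the gene. Ancestral
#' genomes have an empty signature.
#'
#' @param arch A `mito_arch`.
#' @param events Screened events for this genome (confirmed events are
#'   used); computed and default-confirmed when omitted.
#' @return Character vector of signature elements, e.g.
#'   `"inv_tra:trnS1"`, `"deletion:trnP"`, `"duplication:trnP"`; sorted.
#' @export
rearrangement_signature <- function(arch, events = NULL) {
  stopifnot(inherits(arch, "mito_arch"))
  arch <- canonicalize(arch)
  if (is.null(events)) {
    events <- screen_annotation_errors(classify_events(arch), NULL)
  }
  conf <- events[events$status == "confirmed" &
                   events$genome_id == arch$genome_id, , drop = FALSE]
  elems <- character(0)
  for (k in c("duplication", "deletion")) {
    for (s in unique(conf$symbol[conf$kind == k])) {
      elems <- c(elems, paste0(k, ":", s))
    }
  }
  mv <- conf[conf$kind %in% c("inversion", "translocation"), , drop = FALSE]
  if (nrow(mv) > 0L) {
    g <- arch$genes[!arch$genes$pseudo, , drop = FALSE]
    key <- paste(g$symbol, g$copy_index)
    moved <- key %in% paste(mv$symbol, mv$copy_index)
    n <- length(moved)
    if (all(moved)) {
      runs <- list(seq_len(n))
    } else {
      cold <- which(!moved)[1L]
      rot <- c(seq.int(cold, n), if (cold > 1L) seq_len(cold - 1L))
      r <- rle(moved[rot])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- lapply(which(r$values), function(k) rot[starts[k]:ends[k]])
    }
    for (run in runs) {
      lab <- paste0(ifelse(g$sign[run] < 0, "-", ""), g$symbol[run])
      elems <- c(elems, paste0("inv_tra:", paste(lab, collapse = ",")))
    }
  }
  sort(unique(elems))
}

#' Find convergent gene arrangements across taxa
#'
#' Groups genomes sharing an identical non-ancestral canonical architecture
#' (`mode = "whole_architecture"`, the zero-rearrangement-distance
#' criterion) or an identical local rearrangement signature element
#' (`mode = "signature"`, which also captures shared duplications and
#' deletions), and keeps groups spanning at least two distinct taxa at the
#' chosen rank. The rank gate is purely taxonomic: distinguishing true
#' convergence from shared ancestry is left to the user's phylogenetic
#' judgment.
#'
#' @param architectures Named list of `mito_arch` objects.
#' @param taxonomy Taxonomy data.frame covering all genomes.
#' @param rank Grouping rank, `"order"` (default) or `"class"`.
#' @param mode `"signature"` (default) or `"whole_architecture"`.
#' @param events Screened events (required for signature mode with
#'   evidence-based screening; defaults to default-confirmed events).
#' @return Data.frame with one row per convergence group: `element` (key or
#'   signature element), `mode`, `n_genomes`, `n_taxa`, `taxa`
#'   (comma-separated), `genomes` (comma-separated), ordered by group size
#'   descending then element.
#' @export
find_convergences <- function(architectures, taxonomy,
                              rank = c("order", "class"),
                              mode = c("signature", "whole_architecture"),
                              events = NULL) {
  rank <- match.arg(rank)
  mode <- match.arg(mode)
  ids <- vapply(architectures, function(a) a$genome_id, character(1))
  tx <- taxonomy[[rank]][match(ids, taxonomy$genome_id)]
  if (anyNA(tx)) {
    stop("missing taxonomy at rank ", rank, " for: ",
         paste(ids[is.na(tx)], collapse = ", "))
  }

  if (mode == "whole_architecture") {
    keys <- vapply(architectures, architecture_key, character(1))
    pairs <- data.frame(element = keys, genome_id = ids, taxon = tx,
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$element != ancestral_key(), , drop = FALSE]
  } else {
    sig_list <- lapply(architectures, rearrangement_signature, events = events)
    nseg <- lengths(sig_list)
    pairs <- data.frame(element = unlist(sig_list, use.names = FALSE),
                        genome_id = rep(ids, nseg), taxon = rep(tx, nseg),
                        stringsAsFactors = FALSE)
  }
  empty <- data.frame(element = character(), mode = character(),
                      n_genomes = integer(), n_taxa = integer(),
                      taxa = character(), genomes = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  groups <- split(pairs, pairs$element)
  rows <- lapply(groups, function(gr) {
    taxa <- unique(gr$taxon)
    if (length(taxa) < 2L) return(NULL)
    data.frame(element = gr$element[1L], mode = mode,
               n_genomes = nrow(gr), n_taxa = length(taxa),
               taxa = paste(sort(taxa), collapse = ","),
               genomes = paste(sort(gr$genome_id), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_genomes, out$element), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_perm_pair <- function(a, b) {
  stopifnot(inherits(a, "signed_perm"), inherits(b, "signed_perm"))
  if (length(a$values) != length(b$values) ||
      !setequal(abs(a$values), abs(b$values))) {
    stop("permutations have mismatched content")
  }
  if (!identical(a$anchor, b$anchor)) {
    stop("permutations must share the same anchor")
  }
}

#' Breakpoint distance between signed circular permutations
#'
#' The number of signed circular adjacencies of `a` absent from `b`, where
#' an adjacency (x, y) is considered present in `b` also as its
#' reading-direction mirror (-y, -x). Symmetric, non-negative, and zero iff
#' the anchored permutations are identical.
#'
#' @param a,b `signed_perm` objects with the same content and anchor.
#' @return Integer distance.
#' @export
#' @examples
#' p <- to_signed_permutation(ancestral_order())
#' breakpoint_distance(p, p) # 0
breakpoint_distance <- function(a, b) {
  .check_perm_pair(a, b)
  va <- a$values; vb <- b$values
  adj <- function(v) paste(v, c(v[-1L], v[1L]))
  aa <- adj(va)
  bb <- c(adj(vb), adj(-rev(vb)))
  sum(!aa %in% bb)
}

# --- Hannenhalli-Pevzner machinery on the linearized breakpoint graph ------

# Relabel so that b becomes the identity: pi[i] = signed position in b of
# the gene at position i of a.
.relative_perm <- function(a, b) {
  pos <- match(abs(a$values), abs(b$values))
  as.integer(pos * sign(a$values) * sign(b$values[pos]))
}

# Framed doubled representation of a signed permutation of 1..n:
# v[0]=0, each +x -> (2x-1, 2x), each -x -> (2x, 2x-1), v[2n+1]=2n+1.
.framed <- function(pi) {
  n <- length(pi)
  body <- unlist(lapply(pi, function(x) {
    if (x > 0) c(2L * x - 1L, 2L * x) else c(-2L * x, -2L * x - 1L)
  }))
  c(0L, body, 2L * n + 1L)
}

# Breakpoint-graph cycles of a framed permutation. Black edges join
# positions (2i, 2i+1) for i = 0..n (0-based positions); gray edges join
# labels (2j, 2j+1). Returns a list: cycle id per gray edge j = 0..n, cycle
# count, and positions of each label.
.bp_graph <- function(pi) {
  n <- length(pi)
  v <- .framed(pi)
  pos <- integer(2L * n + 2L)          # pos[label + 1] = 0-based position
  pos[v + 1L] <- seq_along(v) - 1L
  # black partner of a label: the label adjacent to it across a black edge
  black <- integer(2L * n + 2L)
  for (i in 0:n) {
    x <- v[2L * i + 1L]; y <- v[2L * i + 2L]
    black[x + 1L] <- y; black[y + 1L] <- x
  }
  # gray partner: 2j <-> 2j+1
  gray <- integer(2L * n + 2L)
  for (j in 0:n) {
    gray[2L * j + 1L] <- 2L * j + 1L
    gray[2L * j + 2L] <- 2L * j
  }
  cyc <- rep(NA_integer_, 2L * n + 2L) # cycle id per label
  ncyc <- 0L
  for (start in 0:(2L * n + 1L)) {
    if (!is.na(cyc[start + 1L])) next
    ncyc <- ncyc + 1L
    cur <- start
    repeat {
      cyc[cur + 1L] <- ncyc
      nxt <- black[cur + 1L]
      cyc[nxt + 1L] <- ncyc
      cur <- gray[nxt + 1L]
      if (cur == start) break
    }
  }
  gray_cycle <- cyc[2L * (0:n) + 1L]   # cycle id of gray edge j (label 2j)
  list(n = n, pos = pos, n_cycles = ncyc, gray_cycle = gray_cycle)
}

# Hurdle count of a framed permutation: unoriented components (no oriented
# gray edge) whose positions form a consecutive block in the circular
# order of unoriented-component positions.
.hp_hurdles <- function(pi, bp = .bp_graph(pi)) {
  n <- bp$n
  jj <- 0:n
  p1 <- bp$pos[2L * jj + 1L]
  p2 <- bp$pos[2L * jj + 2L]
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  oriented_edge <- (p1 %% 2L) == (p2 %% 2L)
  trivial_edge <- hi - lo == 1L
  cyc <- bp$gray_cycle
  # a cycle is trivial iff it has exactly one gray edge and that edge spans 1
  edge_count <- table(cyc)
  trivial_cycle <- as.integer(names(edge_count))[edge_count == 1L]
  trivial_cycle <- trivial_cycle[trivial_cycle %in% cyc[trivial_edge]]
  keep <- !(cyc %in% trivial_cycle)
  if (!any(keep)) return(0L)

  cyc_ids <- unique(cyc[keep])
  # union-find over nontrivial cycles, joined when gray edges interleave
  parent <- seq_along(cyc_ids)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[rx] <<- ry }
  ek <- which(keep)
  for (i in seq_along(ek)) {
    for (j in seq_along(ek)) {
      if (j <= i) next
      e1 <- ek[i]; e2 <- ek[j]
      if (cyc[e1] == cyc[e2]) {
        union_(match(cyc[e1], cyc_ids), match(cyc[e2], cyc_ids))
        next
      }
      crosses <- (lo[e1] < lo[e2] & lo[e2] < hi[e1] & hi[e1] < hi[e2]) ||
        (lo[e2] < lo[e1] & lo[e1] < hi[e2] & hi[e2] < hi[e1])
      if (crosses) union_(match(cyc[e1], cyc_ids), match(cyc[e2], cyc_ids))
    }
  }
  comp_of_cycle <- vapply(seq_along(cyc_ids), find, integer(1))
  comp_of_edge <- comp_of_cycle[match(cyc[keep], cyc_ids)]
  comp_oriented <- tapply(oriented_edge[keep], comp_of_edge, any)
  unor <- as.integer(names(comp_oriented))[!comp_oriented]
  if (length(unor) == 0L) return(0L)
  if (length(unor) == 1L) return(1L)

  # consecutive-block condition on the circle of unoriented positions
  pos_all <- c(p1[keep], p2[keep])
  comp_all <- rep(comp_of_edge, 2L)
  sel <- comp_all %in% unor
  ordp <- order(pos_all[sel])
  seq_comp <- comp_all[sel][ordp]
  collapsed <- rle(seq_comp)$values
  if (length(collapsed) > 1L && collapsed[1L] == collapsed[length(collapsed)]) {
    collapsed <- collapsed[-length(collapsed)]
  }
  sum(vapply(unor, function(u) sum(collapsed == u) == 1L, logical(1)))
}

#' Lower bound on the inversion (reversal) distance
#'
#' Cycle-and-hurdle lower bound on the number of block inversions separating
#' two signed permutations, computed on the breakpoint graph of the anchored
#' linearization: `n + 1 - c + h` where `c` is the cycle count and `h` the
#' hurdle count. This equals the true inversion distance except on
#' fortress-type instances (which require an extra inversion); it is exact
#' on all instances small enough to verify by breadth-first search. Zero
#' iff the permutations are identical, which is the criterion used for
#' whole-architecture convergence.
#'
#' @param a,b `signed_perm` objects with the same content and anchor.
#' @return Integer lower bound.
#' @export
inversion_distance_bound <- function(a, b) {
  .check_perm_pair(a, b)
  pi <- .relative_perm(a, b)
  bp <- .bp_graph(pi)
  as.integer(bp$n + 1L - bp$n_cycles + .hp_hurdles(pi, bp))
}

#' Pairwise distance matrix and zero-distance partition
#'
#' Computes the symmetric breakpoint-distance matrix (optionally also the
#' inversion-distance bound matrix) over a list of signed permutations. The
#' equivalence classes of zero distance are exactly the groups of identical
#' architectures, i.e. the whole-architecture convergence candidates among
#' permutation-complete genomes.
#'
#' @param permutations Named list of `signed_perm` objects.
#' @param inversion Also compute the inversion-bound matrix?
#' @return List with `breakpoint` (integer matrix), `inversion` (or NULL),
#'   and `zero_partition` (integer vector of class ids, named by genome).
#' @export
distance_matrix <- function(permutations, inversion = FALSE) {
  k <- length(permutations)
  ids <- names(permutations)
  if (is.null(ids)) ids <- paste0("g", seq_len(k))
  bp <- matrix(0L, k, k, dimnames = list(ids, ids))
  inv <- if (inversion) bp else NULL
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        bp[i, j] <- bp[j, i] <- breakpoint_distance(permutations[[i]], permutations[[j]])
        if (inversion) {
          inv[i, j] <- inv[j, i] <-
            inversion_distance_bound(permutations[[i]], permutations[[j]])
        }
      }
    }
  }
  # zero-distance equivalence classes
  cls <- integer(k)
  nxt <- 0L
  for (i in seq_len(k)) {
    if (cls[i] != 0L) next
    nxt <- nxt + 1L
    cls[i] <- nxt
    if (i < k) {
      same <- which(cls == 0L & bp[i, ] == 0L)
      cls[same] <- nxt
    }
  }
  names(cls) <- ids
  list(breakpoint = bp, inversion = inv, zero_partition = cls)
}
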