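# Independent oracles and toy builders used across the test files.

.voc <- gene_vocabulary()

# Architecture for a toy signed circular permutation over the first k genes:
# value +i / -i means gene i on its ancestral / opposite strand.
toy_arch <- function(v, id = "toy") {
  architecture(id, .voc$symbol[abs(v)], sign(v) * .voc$sign[abs(v)])
}

# Full-genome architecture from a space-separated signed symbol string.
afs <- function(id, text) mitorearr:::arch_from_string(id, text)

ancestral_string <- paste(
  ifelse(.voc$sign < 0, paste0("-", .voc$symbol), .voc$symbol),
  collapse = " "
)

# Brute-force minimal-removal search: smallest set of gene occurrences whose
# removal leaves a circularly increasing, ancestral-strand order; among the
# maximum kept sets, the one with lexicographically smallest sorted values
# (the same tie-break the package defines). Independent of the DP code path.
brute_moved <- function(v) {
  cand <- which(v > 0)
  vals <- v[cand]
  best_size <- -1L
  best_kept <- integer(0)
  circ_incr <- function(kept) {
    length(kept) <= 2L || sum(diff(c(kept, kept[1L])) < 0) <= 1L
  }
  if (length(cand) > 0L) {
    for (mask in 0:(2^length(cand) - 1L)) {
      sel <- which(bitwAnd(mask, 2^(seq_along(cand) - 1L)) > 0)
      kept <- vals[sel]
      if (length(kept) < best_size || !circ_incr(kept)) next
      if (length(kept) > best_size ||
          paste(sort(kept), collapse = ",") <
          paste(sort(best_kept), collapse = ",")) {
        best_size <- length(kept)
        best_kept <- kept
      }
    }
  }
  sort(setdiff(abs(v), best_kept))
}

# All rotation-class representatives of signed circular permutations of
# 1..n: linear arrangements whose first element is +-1.
signed_circular_reps <- function(n) {
  perm_list <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perm_list(v[-i]), function(p) c(v[i], p))
    }))
  }
  base <- perm_list(seq.int(2L, n))
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- vector("list", length(base) * nrow(signs))
  k <- 0L
  for (p in base) {
    for (s in seq_len(nrow(signs))) {
      k <- k + 1L
      out[[k]] <- c(1L, p) * signs[s, ]
    }
  }
  out
}

# Minimal signed_perm constructor for distance tests.
sperm <- function(v) {
  structure(list(values = as.integer(v), anchor = "toy"),
            class = "signed_perm")
}

# BFS ball of signed linear permutations within `depth` reversals of the
# identity; returns an environment mapping "v1,v2,..." to the exact
# reversal distance.
reversal_ball <- function(n, depth) {
  key <- function(v) paste(v, collapse = ",")
  dist <- new.env(hash = TRUE)
  id <- seq_len(n)
  assign(key(id), 0L, dist)
  frontier <- list(id)
  revs <- do.call(rbind, lapply(seq_len(n), function(i) cbind(i, i:n)))
  for (d in seq_len(depth)) {
    nxt <- list()
    for (v in frontier) {
      for (r in seq_len(nrow(revs))) {
        i <- revs[r, 1L]; j <- revs[r, 2L]
        w <- v
        w[i:j] <- -rev(v[i:j])
        k <- key(w)
        if (is.null(dist[[k]])) {
          dist[[k]] <- d
          nxt[[length(nxt) + 1L]] <- w
        }
      }
    }
    frontier <- nxt
  }
  dist
}

ball_distance <- function(ball, v) {
  d <- ball[[paste(as.integer(v), collapse = ",")]]
  if (is.null(d)) NA_integer_ else d
}

# Apply k random reversals to the identity of size n (linear model).
random_reversal_perm <- function(n, k) {
  v <- seq_len(n)
  for (e in seq_len(k)) {
    ij <- sort(sample.int(n, 2L, replace = TRUE))
    v[ij[1L]:ij[2L]] <- -rev(v[ij[1L]:ij[2L]])
  }
  v
}
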