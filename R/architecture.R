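# Genome architectures: circular, ordered lists of signed gene occurrences.

#' Construct a genome architecture
#'
#' A `mito_arch` holds one genome's circular gene order: for every gene
#' occurrence its canonical symbol, strand sign (+1 heavy, -1 light), copy
#' index (1 for the first or only copy, in coordinate order) and pseudogene
#' flag. Control-region/OL elements are never part of an architecture.
#'
#' @param genome_id Character scalar identifying the genome.
#' @param symbols Character vector of canonical gene symbols, in circular
#'   order.
#' @param signs Integer vector of +1/-1, same length as `symbols`.
#' @param pseudo Logical vector (recycled), pseudogene flags.
#' @param copy_index Optional integer vector; if `NULL`, copies are numbered
#'   in list order per symbol.
#' @param circular Logical; architectures are circular by default.
#' @param source_length_bp Optional genome length in bp.
#' @return An object of class `mito_arch`.
#' @export
#' @examples
#' a <- architecture("toy", c("trnF", "rrnS", "trnV"), c(1L, 1L, 1L))
#' n_genes(a)
architecture <- function(genome_id, symbols, signs, pseudo = FALSE,
                         copy_index = NULL, circular = TRUE,
                         source_length_bp = NA_integer_) {
  if (length(symbols) == 0L) stop("empty architecture")
  bad <- setdiff(unique(symbols), .ANCESTRAL_SYMBOLS)
  if (length(bad) > 0L) {
    stop("unknown gene symbols: ", paste(bad, collapse = ", "))
  }
  signs <- as.integer(signs)
  if (length(signs) != length(symbols) || !all(signs %in% c(-1L, 1L))) {
    stop("signs must be +1/-1 and match symbols in length")
  }
  pseudo <- rep_len(as.logical(pseudo), length(symbols))
  genes <- data.frame(symbol = as.character(symbols), sign = signs,
                      copy_index = NA_integer_, pseudo = pseudo,
                      stringsAsFactors = FALSE)
  if (is.null(copy_index)) {
    genes$copy_index <- stats::ave(seq_along(symbols), symbols,
                                   FUN = seq_along)
  } else {
    genes$copy_index <- as.integer(copy_index)
    if (anyNA(genes$copy_index) || any(genes$copy_index < 1L)) {
      stop("copy_index must be >= 1")
    }
  }
  structure(
    list(genome_id = genome_id, genes = genes, circular = isTRUE(circular),
         source_length_bp = source_length_bp),
    class = "mito_arch"
  )
}

#' @export
print.mito_arch <- function(x, ...) {
  g <- x$genes
  lab <- paste0(ifelse(g$sign < 0, "-", ""), g$symbol,
                ifelse(g$copy_index > 1L, paste0(".", g$copy_index), ""),
                ifelse(g$pseudo, "(psi)", ""))
  cat(sprintf("<mito_arch> %s: %d gene occurrences (circular)\n",
              x$genome_id, nrow(g)))
  cat(" ", paste(lab, collapse = " "), "\n")
  invisible(x)
}

#' Number of gene occurrences in an architecture
#' @param arch A `mito_arch`.
#' @param include_pseudo Count pseudogene copies too?
#' @return Integer.
#' @export
n_genes <- function(arch, include_pseudo = TRUE) {
  if (include_pseudo) nrow(arch$genes) else sum(!arch$genes$pseudo)
}

#' The ancestral vertebrate mitochondrial gene order
#'
#' The fixed 37-gene arrangement shared by most vertebrates, anchored at
#' trnF, with the nine light-strand genes (trnQ, trnA, trnN, trnC, trnY,
#' trnS2, nad6, trnE, trnP) carrying sign -1.
#'
#' @param genome_id Identifier for the returned architecture.
#' @return A `mito_arch` with each canonical symbol exactly once.
#' @export
#' @examples
#' anc <- ancestral_order()
#' anc$genes$symbol[1:2]  # trnF, rrnS
ancestral_order <- function(genome_id = "ancestral") {
  architecture(genome_id, .ANCESTRAL_SYMBOLS, .ANCESTRAL_SIGNS,
               pseudo = FALSE)
}

# Serialize the gene list for key/tie-break purposes.
.arch_tokens <- function(genes) {
  paste0(ifelse(genes$sign < 0, "-", ""), genes$symbol,
         ifelse(genes$pseudo, "~psi", ""))
}

.rotate_rows <- function(df, k) {
  n <- nrow(df)
  if (n == 0L || k %% n == 0L) return(df)
  k <- k %% n
  df[c((k + 1L):n, 1L:k), , drop = FALSE]
}

#' Canonicalize the circular reading frame of an architecture
#'
#' Rotates the circular gene list so that a fixed anchor comes first: the
#' heavy-strand (+) copy of trnF when present, otherwise the present gene
#' with the smallest ancestral index. With several candidate anchor copies,
#' the rotation with the lexicographically smallest serialization is chosen,
#' so the result is invariant under any input rotation. Content-preserving
#' and idempotent.
#'
#' @param arch A `mito_arch`.
#' @return The rotated `mito_arch`.
#' @export
canonicalize <- function(arch) {
  stopifnot(inherits(arch, "mito_arch"))
  g <- arch$genes
  if (nrow(g) == 0L) stop("empty architecture")
  cand <- which(g$symbol == "trnF" & g$sign == 1L & !g$pseudo)
  if (length(cand) == 0L) {
    idx <- .ANCESTRAL_INDEX[g$symbol]
    cand <- which(idx == min(idx))
  }
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(k) {
      paste(.arch_tokens(.rotate_rows(g, k - 1L)), collapse = "|")
    }, character(1))
    cand <- cand[order(keys)][1L]
  }
  arch$genes <- .rotate_rows(g, cand - 1L)
  rownames(arch$genes) <- NULL
  arch
}

#' Is an architecture a complete 37-gene permutation?
#'
#' TRUE when every canonical symbol occurs exactly once among non-pseudo
#' occurrences and there are no pseudogene copies, i.e. the architecture can
#' be encoded as a signed permutation.
#'
#' @param arch A `mito_arch`.
#' @return Logical scalar.
#' @export
is_permutation_complete <- function(arch) {
  g <- arch$genes[!arch$genes$pseudo, ]
  !any(arch$genes$pseudo) &&
    nrow(g) == 37L &&
    length(unique(g$symbol)) == 37L
}

#' Encode an architecture as a signed permutation
#'
#' Each gene is mapped to plus or minus its ancestral index (sign relative
#' to the ancestral strand), so the ancestral architecture maps to the
#' identity (+1, +2, ..., +37). Only permutation-complete architectures (no
#' duplications, no deletions) can be encoded; otherwise an error of class
#' `mitorearr_not_permutation` signals that architecture-level comparison
#' must be used instead.
#'
#' @param arch A `mito_arch`, normally canonicalized.
#' @return An object of class `signed_perm`: list with `values` (37 signed
#'   integers) and `anchor` (the first gene symbol).
#' @export
#' @examples
#' to_signed_permutation(ancestral_order())$values[1:5]
to_signed_permutation <- function(arch) {
  stopifnot(inherits(arch, "mito_arch"))
  if (!is_permutation_complete(arch)) {
    stop(errorCondition(
      sprintf("architecture %s is not permutation-complete (duplicated or missing genes)",
              arch$genome_id),
      class = c("mitorearr_not_permutation", "error", "condition")
    ))
  }
  g <- arch$genes
  idx <- unname(.ANCESTRAL_INDEX[g$symbol])
  anc_sign <- unname(.ANCESTRAL_SIGNS[g$symbol])
  values <- idx * g$sign * anc_sign
  structure(list(values = as.integer(values), anchor = g$symbol[1L]),
            class = "signed_perm")
}

#' @export
print.signed_perm <- function(x, ...) {
  cat("<signed_perm> anchor", x$anchor, "\n ",
      paste(ifelse(x$values > 0, paste0("+", x$values), x$values),
            collapse = " "), "\n")
  invisible(x)
}

# Convenience for tests and examples: parse "trnF rrnS -trnQ trnM.2" style
# strings into an architecture (".2" marks copy index, "~psi" a pseudogene).
arch_from_string <- function(genome_id, text) {
  toks <- strsplit(trimws(text), "[,[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  sign <- ifelse(startsWith(toks, "-"), -1L, 1L)
  toks <- sub("^-", "", toks)
  pseudo <- grepl("~psi$", toks)
  toks <- sub("~psi$", "", toks)
  copy <- rep(NA_integer_, length(toks))
  has_copy <- grepl("\\.\\d+$", toks)
  copy[has_copy] <- as.integer(sub("^.*\\.", "", toks[has_copy]))
  toks <- sub("\\.\\d+$", "", toks)
  symbols <- toks
  ci <- stats::ave(seq_along(symbols), symbols, FUN = seq_along)
  ci[has_copy] <- copy[has_copy]
  architecture(genome_id, symbols, sign, pseudo = pseudo, copy_index = ci)
}
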