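# Canonical 37-gene vocabulary and the ancestral vertebrate gene order.
#
# Index convention: trnF = 1, rrnS = 2, ... around the heavy strand; sign +1
# for heavy-strand genes, -1 for the nine light-strand genes. The control
# region (D-loop) and the light-strand replication origin (OL) are not genes
# and never appear in an architecture.

.ANCESTRAL_SYMBOLS <- c(
  "trnF", "rrnS", "trnV", "rrnL", "trnL1", "nad1", "trnI", "trnQ", "trnM",
  "nad2", "trnW", "trnA", "trnN", "trnC", "trnY", "cox1", "trnS2", "trnD",
  "cox2", "trnK", "atp8", "atp6", "cox3", "trnG", "nad3", "trnR", "nad4L",
  "nad4", "trnH", "trnS1", "trnL2", "nad5", "nad6", "trnE", "cob", "trnT",
  "trnP"
)

.LIGHT_STRAND <- c("trnQ", "trnA", "trnN", "trnC", "trnY", "trnS2",
                   "nad6", "trnE", "trnP")

.ANCESTRAL_SIGNS <- ifelse(.ANCESTRAL_SYMBOLS %in% .LIGHT_STRAND, -1L, 1L)
names(.ANCESTRAL_SIGNS) <- .ANCESTRAL_SYMBOLS

.GENE_CATEGORY <- ifelse(
  startsWith(.ANCESTRAL_SYMBOLS, "trn"), "tRNA",
  ifelse(startsWith(.ANCESTRAL_SYMBOLS, "rrn"), "rRNA", "protein")
)
names(.GENE_CATEGORY) <- .ANCESTRAL_SYMBOLS

.ANCESTRAL_INDEX <- seq_along(.ANCESTRAL_SYMBOLS)
names(.ANCESTRAL_INDEX) <- .ANCESTRAL_SYMBOLS

#' Canonical mitochondrial gene vocabulary
#'
#' The 37 genes of the vertebrate mitochondrial genome: 22 tRNAs, 2 rRNAs and
#' 13 protein-coding genes, listed in the ancestral order (trnF first) with
#' their ancestral strand sign (+1 heavy, -1 light).
#'
#' @return A data.frame with columns `symbol`, `category`, `index`
#'   (ancestral position, 1..37) and `sign` (ancestral strand).
#' @export
#' @examples
#' v <- gene_vocabulary()
#' table(v$category)
gene_vocabulary <- function() {
  data.frame(
    symbol = .ANCESTRAL_SYMBOLS,
    category = unname(.GENE_CATEGORY),
    index = .ANCESTRAL_INDEX,
    sign = unname(.ANCESTRAL_SIGNS),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Synonym table for label normalization. Keys are lower-case with spaces,
# hyphens, underscores and parentheses stripped; values are canonical symbols.
.SYNONYMS <- local({
  syn <- c(
    # proteins
    nad1 = "nad1", nd1 = "nad1", nadh1 = "nad1", nadhdehydrogenasesubunit1 = "nad1",
    nad2 = "nad2", nd2 = "nad2", nadh2 = "nad2", nadhdehydrogenasesubunit2 = "nad2",
    nad3 = "nad3", nd3 = "nad3", nadh3 = "nad3", nadhdehydrogenasesubunit3 = "nad3",
    nad4 = "nad4", nd4 = "nad4", nadh4 = "nad4", nadhdehydrogenasesubunit4 = "nad4",
    nad4l = "nad4L", nd4l = "nad4L", nadh4l = "nad4L", nadhdehydrogenasesubunit4l = "nad4L",
    nad5 = "nad5", nd5 = "nad5", nadh5 = "nad5", nadhdehydrogenasesubunit5 = "nad5",
    nad6 = "nad6", nd6 = "nad6", nadh6 = "nad6", nadhdehydrogenasesubunit6 = "nad6",
    cob = "cob", cytb = "cob", cytochromeb = "cob", cobi = "cob",
    cytochromebapoenzyme = "cob",
    cox1 = "cox1", coi = "cox1", co1 = "cox1", coxi = "cox1",
    cytochromecoxidasesubunit1 = "cox1", cytochromecoxidasesubuniti = "cox1",
    cox2 = "cox2", coii = "cox2", co2 = "cox2", coxii = "cox2",
    cytochromecoxidasesubunit2 = "cox2", cytochromecoxidasesubunitii = "cox2",
    cox3 = "cox3", coiii = "cox3", co3 = "cox3", coxiii = "cox3",
    cytochromecoxidasesubunit3 = "cox3", cytochromecoxidasesubunitiii = "cox3",
    atp6 = "atp6", atpase6 = "atp6", atpsynthasef0subunit6 = "atp6",
    atpsynthase6 = "atp6",
    atp8 = "atp8", atpase8 = "atp8", atpsynthasef0subunit8 = "atp8",
    atpsynthase8 = "atp8",
    # rRNAs
    rrns = "rrnS", "12s" = "rrnS", "12srrna" = "rrnS", "12sribosomalrna" = "rrnS",
    srrna = "rrnS", ssurrna = "rrnS", smallsubunitribosomalrna = "rrnS",
    rrnl = "rrnL", "16s" = "rrnL", "16srrna" = "rrnL", "16sribosomalrna" = "rrnL",
    lrrna = "rrnL", lsurrna = "rrnL", largesubunitribosomalrna = "rrnL"
  )
  # tRNAs by amino acid
  aa <- c(
    phe = "trnF", val = "trnV", ile = "trnI", gln = "trnQ", met = "trnM",
    trp = "trnW", ala = "trnA", asn = "trnN", cys = "trnC", tyr = "trnY",
    asp = "trnD", lys = "trnK", gly = "trnG", arg = "trnR", his = "trnH",
    glu = "trnE", thr = "trnT", pro = "trnP"
  )
  for (a in names(aa)) {
    syn[paste0("trna", a)] <- aa[[a]]
    syn[tolower(aa[[a]])] <- aa[[a]]
  }
  # leucine / serine need the codon family to be unambiguous
  syn["trnauur"] <- "trnL1"; syn["trnaleuuur"] <- "trnL1"; syn["trnl1"] <- "trnL1"
  syn["trnluur"] <- "trnL1"
  syn["trnacun"] <- "trnL2"; syn["trnaleucun"] <- "trnL2"; syn["trnl2"] <- "trnL2"
  syn["trnlcun"] <- "trnL2"
  syn["trnaseragy"] <- "trnS1"; syn["trns1"] <- "trnS1"; syn["trnsagy"] <- "trnS1"
  syn["trnasergcu"] <- "trnS1"
  syn["trnaserucn"] <- "trnS2"; syn["trns2"] <- "trnS2"; syn["trnsucn"] <- "trnS2"
  syn["trnaseruga"] <- "trnS2"
  syn
})

.AMBIGUOUS_LABELS <- c("trnaleu", "trnl", "trnaser", "trns")

.NONCODING_PATTERNS <- c(
  "dloop", "d-loop", "controlregion", "misc", "oh", "ol",
  "lstrandorigin", "originoflstrandreplication", "replicationorigin",
  "lightstrandorigin"
)

.squash_label <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

# TRUE for labels naming the control region / replication origins, which are
# stripped from architectures rather than treated as unmapped.
is_noncoding_label <- function(raw_label) {
  s <- .squash_label(raw_label)
  s %in% .NONCODING_PATTERNS | grepl("^dloop|^controlregion|^repori|^originofreplication", s)
}

#' Normalize a raw annotation label to the canonical gene symbol
#'
#' Maps common GenBank gene/product synonyms (e.g. `CYTB`, `ND6`,
#' `tRNA-Phe`, `12S ribosomal RNA`, `COI`) to the canonical 37-gene
#' vocabulary. Leucine and serine tRNAs require a codon-family qualifier
#' (`UUR`/`CUN`, `AGY`/`UCN`) or an explicit `trnL1`/`trnL2`/`trnS1`/`trnS2`
#' label; a bare `tRNA-Leu` or `tRNA-Ser` raises an ambiguity error so the
#' caller can resolve it from neighbour context (see
#' [build_architecture()]).
#'
#' @param raw_label Character scalar, the annotation label as found in the
#'   source record.
#' @param feature_class One of `"gene"`, `"tRNA"`, `"rRNA"`, `"CDS"`; used
#'   only for error messages.
#' @return Canonical gene symbol (character scalar).
#' @export
#' @examples
#' normalize_gene_symbol("CYTB", "CDS")
#' normalize_gene_symbol("tRNA-Phe", "tRNA")
normalize_gene_symbol <- function(raw_label, feature_class = "gene") {
  if (length(raw_label) != 1L || is.na(raw_label) || !nzchar(raw_label)) {
    stop("raw_label must be a non-empty character scalar")
  }
  s <- .squash_label(raw_label)
  if (s %in% .AMBIGUOUS_LABELS) {
    stop(errorCondition(
      sprintf("ambiguous leucine/serine tRNA label '%s' (no codon family)", raw_label),
      raw_label = raw_label,
      class = c("mitorearr_ambiguous_symbol", "mitorearr_unmapped_label", "error", "condition")
    ))
  }
  hit <- .SYNONYMS[s]
  if (is.na(hit)) {
    stop(errorCondition(
      sprintf("unmapped label '%s' (feature class %s)", raw_label, feature_class),
      raw_label = raw_label,
      class = c("mitorearr_unmapped_label", "error", "condition")
    ))
  }
  unname(hit)
}
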