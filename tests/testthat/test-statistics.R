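test_that("per-taxon proportion follows NRo/(NE*37)*100 with half-up rounding", {
  expect_equal(proportion_taxon(6, 6), 2.70)
  expect_equal(proportion_taxon(0, 100), 0)
  expect_equal(proportion_taxon(37 * 12, 12), 100)
  expect_equal(proportion_taxon(751, 1259), 1.61)
  expect_error(proportion_taxon(1, 0), "NE")
  expect_error(proportion_taxon(-1, 5), "NRo")
  # linear in NRo, inverse-linear in NE
  expect_equal(proportion_taxon(50, 10), proportion_taxon(100, 20))
})

test_that("per-gene proportion follows NRg/NE*100 and flags values over 100", {
  expect_equal(proportion_gene(0, 12), 0)
  expect_equal(proportion_gene(1, 1), 100)
  expect_equal(proportion_gene(9, 37), 24.32)
  expect_warning(out <- proportion_gene(3, 2), "exceeds 100")
  expect_equal(out, 150)
})

test_that("half-up rounding differs from round-half-even where it matters", {
  expect_equal(round_half_up(2.705, 2), 2.71)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(87.25, 1), 87.3)
})

test_that("summary rows satisfy the bookkeeping identities", {
  taxonomy <- data.frame(
    genome_id = c("g1", "g2", "g3"), species = paste0("s", 1:3),
    class = c("C1", "C1", "C2"), order = c("O1", "O1", "O2"),
    stringsAsFactors = FALSE
  )
  events <- rbind(
    data.frame(genome_id = "g1", symbol = c("trnP", "trnT", "trnE"),
               copy_index = 1L,
               kind = c("translocation", "translocation", "inversion"),
               reported_class = "inv_tra",
               status = c("confirmed", "confirmed", "refuted"),
               reason = c("none", "none", "wrong_strand_annotation"),
               stringsAsFactors = FALSE),
    data.frame(genome_id = "g3", symbol = "trnM", copy_index = 2L,
               kind = "duplication", reported_class = "dup",
               status = "confirmed", reason = "none", stringsAsFactors = FALSE)
  )
  s <- summarize_rearrangements(events, taxonomy, rank = "class")
  expect_equal(s$taxon, c("C1", "C2", "Total"))
  expect_equal(s$genes_differing, s$n_confirmed + s$n_refuted)
  expect_equal(s$n_confirmed, s$n_dup + s$n_del + s$n_inv_tra)
  # 2 species, 3 differing genes in C1
  expect_equal(s$pct_reorganization[1L], proportion_taxon(3, 2))
  expect_equal(s$pct_reorganization[1L], round_half_up(3 / (2 * 37) * 100, 2))
  # totals row sums the class rows
  expect_equal(s$n_species[3L], sum(s$n_species[1:2]))
  expect_equal(s$genes_differing[3L], sum(s$genes_differing[1:2]))
  # confirmed-only selector
  sc <- summarize_rearrangements(events, taxonomy, "class", "confirmed")
  expect_equal(sc$pct_reorganization[1L], proportion_taxon(2, 2))
  # empty event set gives all-zero rows
  s0 <- summarize_rearrangements(events[0, ], taxonomy, "class")
  expect_true(all(s0$genes_differing == 0L))
  expect_true(all(s0$pct_reorganization == 0))
  expect_error(summarize_rearrangements(
    data.frame(genome_id = "nope", symbol = "trnP", copy_index = 1L,
               kind = "deletion", reported_class = "del", status = "confirmed",
               reason = "none"), taxonomy), "missing taxonomy")
})

test_that("event breakdown reports percentages that sum to 100", {
  mk <- function(n, class, symbol) {
    if (n == 0) return(NULL)
    data.frame(genome_id = sprintf("g%04d", seq_len(n)), symbol = symbol,
               copy_index = 1L,
               kind = switch(class, dup = "duplication", del = "deletion",
                             inv_tra = "translocation"),
               reported_class = class, status = "confirmed", reason = "none",
               stringsAsFactors = FALSE)
  }
  events <- rbind(mk(4, "dup", "trnM"))
  b <- event_breakdown(events)
  expect_equal(b$by_class$pct[b$by_class$reported_class == "dup"], 100)
  events <- rbind(mk(68, "dup", "trnT"), mk(4, "del", "trnP"))
  b <- event_breakdown(events)
  expect_equal(b$by_class$pct, c(0, 94.4, 5.6))
  expect_lte(abs(sum(b$by_class$pct) - 100), 0.2)
  expect_lte(abs(sum(b$by_category$pct) - 100), 0.2)
  # zero confirmed events: empty tables, no division error
  none <- mk(3, "dup", "trnM")
  none$status <- "refuted"
  b0 <- event_breakdown(none)
  expect_equal(nrow(b0$by_class), 0L)
  expect_equal(b0$n_confirmed, 0L)
})

test_that("gene matrix has deterministic order/gene axes and PRg cells", {
  taxonomy <- data.frame(genome_id = c("g1", "g2"), species = c("s1", "s2"),
                         class = "C", order = c("O1", "O2"),
                         stringsAsFactors = FALSE)
  events <- data.frame(genome_id = "g1", symbol = "trnP", copy_index = 1L,
                       kind = "translocation", reported_class = "inv_tra",
                       status = "confirmed", reason = "none",
                       stringsAsFactors = FALSE)
  m <- gene_matrix(events, taxonomy)
  expect_equal(rownames(m), "O1")
  expect_equal(colnames(m), gene_vocabulary()$symbol)
  expect_equal(m["O1", "trnP"], 100)
  expect_equal(sum(m), 100)
  # two orders sharing no events: block-diagonal nonzeros
  events2 <- rbind(events, within(events, { genome_id <- "g2"; symbol <- "trnM" }))
  m2 <- gene_matrix(events2, taxonomy)
  expect_equal(m2["O1", "trnM"], 0)
  expect_equal(m2["O2", "trnM"], 100)
  expect_equal(m2["O2", "trnP"], 0)
})

test_that("hotspot detection finds the three rearrangement clusters", {
  v <- gene_vocabulary()$symbol
  totals <- setNames(rep(0, 37), v)
  totals[c("trnL1", "nad1", "trnI", "trnQ", "trnM")] <- c(103, 101, 145, 70, 58)
  totals[c("trnW", "trnA", "trnN", "trnC")] <- c(55, 56, 56, 60)
  totals[c("trnH", "trnS1", "trnL2", "nad5", "nad6", "trnE", "cob", "trnT",
           "trnP")] <- c(38, 44, 108, 30, 70, 80, 50, 81, 85)
  totals[c("cox2", "trnK", "atp8", "atp6", "cox3", "trnG", "nad3", "trnR",
           "nad4L", "nad4")] <- c(9, 13, 11, 10, 9, 11, 10, 12, 10, 12)
  hs <- hotspot_regions(totals, min_run = 2, threshold = 30)
  expect_equal(nrow(hs), 3L)
  expect_setequal(hs$genes, c(
    "trnL1,nad1,trnI,trnQ,trnM",
    "trnW,trnA,trnN,trnC",
    "trnH,trnS1,trnL2,nad5,nad6,trnE,cob,trnT,trnP"
  ))
  # the conserved cox2..nad4 block is excluded
  expect_false(any(grepl("cox2", hs$genes)))

  expect_equal(nrow(hotspot_regions(rep(0, 37), threshold = 1)), 0L)
  # an isolated hot gene fails the min_run gate
  single <- rep(0, 37); single[10] <- 99
  expect_equal(nrow(hotspot_regions(single, min_run = 2, threshold = 30)), 0L)
  expect_equal(nrow(hotspot_regions(single, min_run = 1, threshold = 30)), 1L)
  # a run wrapping the circular origin is kept intact
  wrap <- rep(0, 37); wrap[c(36, 37, 1, 2)] <- 50
  hw <- hotspot_regions(wrap, min_run = 2, threshold = 30)
  expect_equal(nrow(hw), 1L)
  expect_equal(hw$length, 4L)
  expect_equal(hw$genes, "trnT,trnP,trnF,rrnS")
})
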